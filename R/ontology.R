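# Minimal ontology support: a directed acyclic graph of terms (child ->
# parents over is_a / part_of), read from OBO flat files or built in code.

#' Build an ontology DAG
#'
#' @param terms tibble with columns `id` and `name`.
#' @param parents named list: term id -> character vector of parent ids.
#' @return An object of class `cyclo_ontology`.
#' @export
ontology <- function(terms, parents) {
  stopifnot(all(c("id", "name") %in% names(terms)))
  parents <- parents[intersect(names(parents), terms$id)]
  missing <- setdiff(terms$id, names(parents))
  parents[missing] <- list(character())
  bad <- setdiff(unique(unlist(parents)), terms$id)
  if (length(bad) > 0) {
    abort(paste0("parent ids missing from terms: ", paste(bad, collapse = ", ")))
  }
  ont <- structure(list(terms = terms, parents = parents), class = "cyclo_ontology")
  term_ancestors(ont) # walks the full graph; errors on a cycle
  ont
}

#' Read an OBO-format ontology
#'
#' Parses `[Term]` stanzas keeping `id`, `name`, `is_a` and
#' `relationship: part_of` edges (the edge set is configurable); obsolete
#' terms are dropped.
#'
#' @param path path to an OBO file.
#' @param relations relationship types treated as parent edges in addition to
#'   `is_a`.
#' @return A `cyclo_ontology`.
#' @export
read_obo <- function(path, relations = "part_of") {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <<- cur
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(cur)
      cur <- list(parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3) next
      key <- kv[2]
      val <- trimws(kv[3])
      if (key == "id") cur$id <- val
      if (key == "name") cur$name <- val
      if (key == "is_a") cur$parents <- c(cur$parents, val)
      if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
      if (key == "relationship") {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) >= 2 && parts[1] %in% relations) {
          cur$parents <- c(cur$parents, parts[2])
        }
      }
    }
  }
  flush(cur)
  ids <- names(terms)
  ontology(tibble(id = ids,
                  name = map_chr(terms, ~ .x$name %||% NA_character_)),
           map(terms, ~ intersect(unique(.x$parents), ids)))
}

# all ancestors (excluding the term itself) for every term; errors on cycles
term_ancestors <- function(ont) {
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  rec <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (!is.null(visiting[[id]])) abort(paste0("ontology graph has a cycle at ", id))
    visiting[[id]] <- TRUE
    anc <- unique(unlist(c(ont$parents[[id]],
                           lapply(ont$parents[[id]], rec)))) %||% character()
    rm(list = id, envir = visiting)
    memo[[id]] <- anc
    anc
  }
  setNames(lapply(ont$terms$id, rec), ont$terms$id)
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' @param ann tibble with columns `gene_id` and `term`.
#' @param ont a `cyclo_ontology`.
#' @return The closed annotation tibble: every gene annotated to a term is
#'   annotated to all of its ancestors.
#' @export
propagate_annotations <- function(ann, ont) {
  stopifnot(all(c("gene_id", "term") %in% names(ann)))
  bad <- setdiff(unique(ann$term), ont$terms$id)
  if (length(bad) > 0) {
    abort(paste0("annotations use unknown terms: ", paste(bad, collapse = ", ")))
  }
  anc <- term_ancestors(ont)
  extra <- ann |>
    mutate(term = map(.data$term, ~ c(.x, anc[[.x]]))) |>
    tidyr::unnest("term")
  distinct(extra, .data$gene_id, .data$term)
}
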