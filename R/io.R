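#' Read and write expression time-course TSVs
#'
#' The format is a plain TSV: first column the gene id, remaining columns
#' one per time point with headers giving the time in hours (`t2.00`,
#' `t2.75`, ...; a bare numeric header is also accepted). Ragged rows,
#' duplicate ids, non-numeric cells and negative values are rejected with
#' coordinates.
#'
#' @param path file path.
#' @return A time-course tibble (see [timecourse()]).
#' @export
read_expression_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected a gene-id column plus time columns")
  times <- suppressWarnings(as.numeric(sub("^t", "", names(raw)[-1])))
  if (anyNA(times)) {
    abort(paste0("unparseable time headers: ",
                 paste(names(raw)[-1][is.na(times)], collapse = ", ")))
  }
  vals <- suppressWarnings(vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric value at row %d (gene %s), column %s",
                  bad[1], raw[[1]][bad[1]], names(raw)[bad[2] + 1]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative expression at row %d (gene %s), column %s",
                  bad[1], raw[[1]][bad[1]], names(raw)[bad[2] + 1]))
  }
  timecourse(raw[[1]], vals, times)
}

#' @rdname read_expression_tsv
#' @param tc a time-course tibble.
#' @export
write_expression_tsv <- function(tc, path) {
  validate_timecourse(tc)
  readr::write_tsv(tc, path)
  invisible(path)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' First column the orthogroup id, one column per species containing
#' comma-separated gene ids (empty cell = the orthogroup is absent from that
#' species). Returned in long form.
#'
#' @param path file path.
#' @return A tibble with columns `orthogroup`, `species`, `gene_id`.
#' @export
read_orthogroups_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected an orthogroup column plus species columns")
  names(raw)[1] <- "orthogroup"
  long <- raw |>
    tidyr::pivot_longer(-"orthogroup", names_to = "species", values_to = "gene_id") |>
    filter(!is.na(.data$gene_id), .data$gene_id != "") |>
    mutate(gene_id = strsplit(.data$gene_id, ",\\s*")) |>
    tidyr::unnest("gene_id")
  dup <- long |>
    count(.data$species, .data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("genes in more than one orthogroup: ",
                 paste(head(dup$gene_id, 5), collapse = ", ")))
  }
  long
}

#' Read a one-gene-per-line list
#'
#' @param path file path.
#' @return Character vector of gene ids (blank lines and `#` comments dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a node-to-age map
#'
#' Two- or three-column TSV: node label, integer age class, optional label.
#'
#' @param path file path.
#' @return Tibble with columns `node`, `age`, `age_label`.
#' @export
read_node_age_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expected columns: node, age[, age_label]")
  tibble(node = raw[[1]], age = as.integer(raw[[2]]),
         age_label = if (ncol(raw) >= 3) raw[[3]] else as.character(raw[[2]]))
}

#' Flat key=value configuration files
#'
#' Round-trips a flat named list through a `key=value` text file; numeric and
#' logical values are restored, comma-separated values become vectors.
#'
#' @param config a named list of scalars or atomic vectors.
#' @param path file path.
#' @export
write_flat_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  lines <- map_chr(names(config), function(k) {
    paste0(k, "=", paste(config[[k]], collapse = ","))
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flat_config
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) abort(paste0("malformed config line: ", ln))
    vals <- strsplit(kv[3], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[trimws(kv[2])]] <- if (!anyNA(num)) {
      if (all(num == round(num)) && all(abs(num) < 2^31)) as.integer(num) else num
    } else if (all(vals %in% c("TRUE", "FALSE"))) {
      as.logical(vals)
    } else vals
  }
  out
}
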