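#' Read a beta-value matrix from delimited text
#'
#' Reads an Illumina-style methylation matrix (beta values, i.e. methylation
#' fractions in \[0,1\]) from CSV or TSV. The common array export shape —
#' probes in rows, one column per sample, first column the CpG probe ID —
#' is the default dialect; `samples_in_rows` reads the transposed layout.
#' Empty cells and `NA` are treated as missing. Values outside \[0,1\] are
#' an error naming the offending probe and sample; probe identifiers that do
#' not look like CpG IDs (`cg` followed by digits) produce a warning only,
#' since custom probe namespaces are legitimate.
#'
#' @param path Path to a delimited text file with a header row. Comma or tab
#'   delimited (sniffed from the header line).
#' @param dialect `"probes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A beta tibble: column `probe_id` plus one numeric column per
#'   sample. Probe and sample identifiers are guaranteed unique and all
#'   non-missing values lie in \[0,1\].
#' @seealso [write_beta_matrix()], [intersect_platforms()]
#' @export
read_beta_matrix <- function(path, dialect = c("probes_in_rows", "samples_in_rows")) {
  dialect <- arg_match(dialect)
  tbl <- read_delimited(path)
  if (dialect == "samples_in_rows") {
    ids <- names(tbl)[-1]
    samples <- as.character(tbl[[1]])
    vals <- t(as.matrix(tbl[, -1, drop = FALSE]))
    tbl <- tibble::tibble(probe_id = ids)
    mat <- matrix(as.numeric(vals), nrow = length(ids),
                  dimnames = list(NULL, samples))
    tbl <- dplyr::bind_cols(tbl, as_tibble(mat))
  } else {
    names(tbl)[1] <- "probe_id"
    tbl$probe_id <- as.character(tbl$probe_id)
  }
  validate_beta(tbl)
}

#' Write a beta tibble to delimited text
#'
#' Inverse of [read_beta_matrix()] for the probes-in-rows dialect. Missing
#' values are written as empty cells. `read_beta_matrix(write_beta_matrix(x))`
#' is the identity up to float formatting (15 significant digits).
#'
#' @param beta A beta tibble (see [read_beta_matrix()]).
#' @param path Output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- validate_beta(beta)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(beta, path, delim = delim, na = "")
  invisible(path)
}

#' Validate a beta tibble
#'
#' Checks the container invariants for methylation fraction tables: unique
#' probe and sample identifiers, numeric sample columns, and all non-missing
#' values in \[0,1\]. Returns the validated tibble so it can be piped.
#'
#' @param beta A data frame with a `probe_id` column and numeric sample
#'   columns.
#' @return The input as a validated tibble.
#' @export
validate_beta <- function(beta) {
  if (!is.data.frame(beta) || !"probe_id" %in% names(beta)) {
    abort("A beta matrix needs a `probe_id` column plus sample columns.")
  }
  beta <- as_tibble(beta)
  beta <- dplyr::relocate(beta, "probe_id")
  probes <- beta$probe_id
  samples <- setdiff(names(beta), "probe_id")
  if (length(samples) == 0) abort("Beta matrix has no sample columns.")
  if (anyDuplicated(probes)) {
    abort(sprintf("Duplicate probe identifiers: %s.",
                  paste(unique(probes[duplicated(probes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort("Duplicate sample identifiers in header.")
  }
  odd <- probes[!grepl("^cg[0-9]+$", probes)]
  if (length(odd) > 0) {
    warn(sprintf("%d probe ID(s) do not match the 'cg<digits>' pattern (e.g. %s).",
                 length(odd), odd[1]))
  }
  for (s in samples) {
    v <- beta[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("Sample column '%s' is not numeric.", s))
    }
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      abort(sprintf(
        "Beta value out of [0,1]: probe '%s', sample '%s', value %g.",
        probes[bad[1]], s, v[bad[1]]
      ))
    }
  }
  beta
}

#' Convert a beta tibble to a probes-by-samples matrix
#'
#' @param beta A beta tibble.
#' @return A numeric matrix with probe IDs as rownames and sample IDs as
#'   colnames.
#' @export
beta_to_matrix <- function(beta) {
  beta <- validate_beta(beta)
  m <- as.matrix(beta[, setdiff(names(beta), "probe_id"), drop = FALSE])
  rownames(m) <- beta$probe_id
  m
}

#' Read a platform probe manifest
#'
#' A manifest is a plain-text file with one probe ID per line, describing
#' the probe universe of an array platform (e.g. 450K or EPIC).
#'
#' @param path Path to the manifest file.
#' @param platform Optional platform label; defaults to the file name.
#' @return Character vector of unique probe IDs with attribute `platform`.
#' @export
read_manifest <- function(path, platform = basename(path)) {
  ids <- readr::read_lines(path)
  ids <- ids[nzchar(trimws(ids))]
  ids <- trimws(ids)
  if (length(ids) == 0) abort(sprintf("Manifest '%s' is empty.", path))
  ids <- unique(ids)
  attr(ids, "platform") <- platform
  ids
}

#' Restrict a beta matrix to probes shared across platforms
#'
#' Clocks meant to run on both the 450K and EPIC arrays are trained only on
#' probes present on every platform. Given one or more manifests (character
#' vectors of probe IDs, see [read_manifest()]), keeps the probes of `beta`
#' that appear in every manifest, preserving the original probe order. The
#' operation is idempotent and does not depend on manifest order.
#'
#' @param beta A beta tibble.
#' @param manifests A character vector of probe IDs, or a list of them.
#' @return The restricted beta tibble.
#' @export
intersect_platforms <- function(beta, manifests) {
  beta <- validate_beta(beta)
  if (is.character(manifests)) manifests <- list(manifests)
  if (!is.list(manifests) || length(manifests) == 0) {
    abort("Provide at least one manifest (character vector of probe IDs).")
  }
  keep <- beta$probe_id
  for (m in manifests) keep <- keep[keep %in% m]
  if (length(keep) == 0) {
    abort(paste(
      "No probes of the beta matrix are present on every platform manifest.",
      "Check that the manifests use the same probe-ID namespace as the data."
    ))
  }
  beta[match(keep, beta$probe_id), , drop = FALSE]
}

#' Read a sample annotation table
#'
#' Reads the per-sample metadata used in clock training and age-acceleration
#' analysis. Required columns: `sample_id`, `age` (years). Optional columns:
#' `sex` (`male`/`female`/`unknown`), `tissue`, `disease` (the label
#' `"control"` is reserved for reference samples), `pdl` (cumulative
#' population doubling level). Ages must exceed -1 (slightly negative
#' gestational offsets for cord blood are allowed); `pdl` must be finite and
#' non-negative when present.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_sample_annotation <- function(path) {
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

#' Validate a sample annotation tibble
#'
#' @param ann A data frame with at least `sample_id` and `age` columns.
#' @return The validated tibble (with `sex` normalised if present).
#' @export
validate_annotation <- function(ann) {
  if (!is.data.frame(ann)) abort("Annotation must be a data frame.")
  ann <- as_tibble(ann)
  miss <- setdiff(c("sample_id", "age"), names(ann))
  if (length(miss) > 0) {
    abort(sprintf("Annotation is missing required column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) abort("Duplicate sample_id in annotation.")
  if (!is.numeric(ann$age)) abort("`age` must be numeric (years).")
  bad <- which(!is.na(ann$age) & ann$age <= -1)
  if (length(bad) > 0) {
    abort(sprintf("Age must be > -1; sample '%s' has age %g.",
                  ann$sample_id[bad[1]], ann$age[bad[1]]))
  }
  if ("sex" %in% names(ann)) {
    sx <- tolower(as.character(ann$sex))
    sx[sx %in% c("m", "male")] <- "male"
    sx[sx %in% c("f", "female")] <- "female"
    sx[is.na(sx) | !sx %in% c("male", "female")] <- "unknown"
    ann$sex <- sx
  }
  if ("pdl" %in% names(ann)) {
    bad <- which(!is.na(ann$pdl) & (!is.finite(ann$pdl) | ann$pdl < 0))
    if (length(bad) > 0) {
      abort(sprintf("`pdl` must be finite and >= 0; sample '%s' has %g.",
                    ann$sample_id[bad[1]], ann$pdl[bad[1]]))
    }
  }
  ann
}

# Sniff delimiter from header line, read with readr, fail loudly on parse
# problems (naming the first offending line).
read_delimited <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  if (length(header) == 0) abort(sprintf("File '%s' is empty.", path))
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  ))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("Parse error in '%s' at line %d: expected %s, got '%s'.",
                  path, prob$row[1] + 1, prob$expected[1], prob$actual[1]))
  }
  # any sample column that came in as character means non-numeric tokens
  for (j in seq_along(tbl)[-1]) {
    if (!is.numeric(tbl[[j]])) {
      v <- suppressWarnings(as.numeric(tbl[[j]]))
      bad <- which(is.na(v) & !is.na(tbl[[j]]) & nzchar(trimws(tbl[[j]])))
      if (length(bad) > 0) {
        abort(sprintf("Parse error in '%s' at line %d: non-numeric value '%s' in column '%s'.",
                      path, bad[1] + 1, tbl[[j]][bad[1]], names(tbl)[j]))
      }
      tbl[[j]] <- v
    }
  }
  tbl
}
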