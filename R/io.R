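# File formats: nuclei tables (CSV with a comment header), the
# persisted module (JSON), and QC report streams (JSON lines + CSV).

#' Write a nuclei table to CSV
#'
#' Comma-separated, UTF-8, header row; slide dimensions and pipeline
#' identifier are stored in leading `#` comment lines so the elliptic
#' interior filter can be applied on re-read.
#'
#' @param batch A `wsi_batch` (or nuclei tibble with batch attributes).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nuclei_table <- function(batch, path) {
  dims <- resolve_dims(batch, NULL)
  pid <- attr(batch, "pipeline_id") %||% "unknown"
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(c(sprintf("# pipeline_id: %s", pid),
               sprintf("# wsi_dims: %.10g %.10g",
                       dims[["width"]], dims[["height"]])), con)
  close(con)
  df <- as_tibble(batch)
  df$is_debris <- as.integer(df$is_debris)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- list(pipeline_id = NA_character_, wsi_dims = NULL)
  for (ln in lines[startsWith(lines, "#")]) {
    if (grepl("^#\\s*pipeline_id:", ln)) {
      meta$pipeline_id <- trimws(sub("^#\\s*pipeline_id:", "", ln))
    } else if (grepl("^#\\s*wsi_dims:", ln)) {
      vals <- as.numeric(strsplit(trimws(sub("^#\\s*wsi_dims:", "", ln)),
                                  "\\s+")[[1]])
      meta$wsi_dims <- c(width = vals[1], height = vals[2])
    }
  }
  meta
}

#' Read nuclei tables into a batch
#'
#' Reads one or more nuclei CSV files (as written by
#' [write_nuclei_table()]) and assembles them into a single batch. The
#' schema — `wsi_id`, `x`, `y`, `is_debris`, then `f_...` feature
#' columns — is validated; inconsistent feature columns across files
#' and non-finite values are rejected with the offending file, column
#' or row named.
#'
#' @param paths Character vector of file paths.
#' @return A `wsi_batch`.
#' @export
read_nuclei_tables <- function(paths) {
  if (length(paths) == 0L) abort("`paths` must name at least one file.")
  required <- c("wsi_id", "x", "y", "is_debris")
  tables <- lapply(paths, function(p) {
    df <- readr::read_csv(p, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      abort(sprintf("File '%s' is missing required column(s): %s.",
                    p, paste(missing, collapse = ", ")))
    }
    fcols <- feature_cols(df)
    if (length(fcols) == 0L) {
      abort(sprintf("File '%s' carries no feature columns (f_...).", p))
    }
    if (!all(df$is_debris %in% c(0L, 1L))) {
      abort(sprintf("File '%s': `is_debris` must be 0/1.", p))
    }
    fm <- as.matrix(df[, fcols])
    if (any(!is.finite(fm))) {
      bad <- which(!is.finite(fm), arr.ind = TRUE)[1, ]
      abort(sprintf("File '%s': non-finite feature value at row %d, column %s.",
                    p, bad[1], fcols[bad[2]]))
    }
    df$is_debris <- as.logical(df$is_debris)
    df$wsi_id <- as.character(df$wsi_id)
    df
  })
  fcols1 <- feature_cols(tables[[1]])
  for (k in seq_along(tables)[-1]) {
    if (!identical(feature_cols(tables[[k]]), fcols1)) {
      abort(sprintf("File '%s' has feature columns inconsistent with '%s'.",
                    paths[k], paths[1]))
    }
  }
  out <- dplyr::bind_rows(tables)
  meta <- read_header_meta(paths[1])
  attr(out, "pipeline_id") <- meta$pipeline_id
  attr(out, "wsi_dims") <- meta$wsi_dims %||% c(width = 1, height = 1)
  class(out) <- unique(c("wsi_batch", class(out)))
  out
}

#' Serialize a calibrated module to JSON
#'
#' Writes a single JSON document holding the format version, the
#' parameter combination, beta, the normalization bounds, and for each
#' reference its identifier, reduction index list, histogram columns
#' and weight. The document round-trips bit-identically through
#' [read_qc_module()].
#'
#' @param module A calibrated `qc_module`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_module <- function(module, path) {
  stopifnot(inherits(module, "qc_module"))
  refs <- lapply(module$references, function(ref) {
    list(id = ref$id,
         reduction = ref$P$idx,
         alpha = ref$alpha,
         diagonal_distance = ref$diagonal_distance,
         histogram = unname(apply(unclass(ref$R), 2, as.numeric,
                                  simplify = FALSE)),
         histogram_features = colnames(ref$R))
  })
  doc <- list(
    format_version = 1L,
    params = unclass(module$params),
    beta = module$beta,
    n_bin = module$n_bin,
    distance = unclass(module$distance_spec),
    feature_ids = module$bounds$feature_ids,
    bounds = list(lower = unname(module$bounds$lower),
                  upper = unname(module$bounds$upper)),
    references = unname(refs),
    D = unname(apply(module$D, 1, as.numeric, simplify = FALSE)),
    merge_groups = module$merge_groups,
    alerts = module$alerts
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a calibrated module from JSON
#'
#' Inverse of [write_qc_module()]. Histogram columns are checked for
#' column-stochasticity on load.
#'
#' @param path A module JSON file.
#' @return A `qc_module`.
#' @export
read_qc_module <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  p <- doc$params
  params <- param_combination(
    n_wsi = p$n_wsi, n_nuc = p$n_nuc,
    intern_tau = p$intern_tau %||% NA,
    use_distrib = isTRUE(p$use_distrib),
    omega = p$omega, aggregator = p$aggregator,
    sel_method = p$sel_method,
    n_sel = p$n_sel %||% NA, seed = p$seed,
    use_debris = isTRUE(p$use_debris))
  fids <- doc$feature_ids
  bounds <- structure(
    list(lower = setNames(doc$bounds$lower, fids),
         upper = setNames(doc$bounds$upper, fids),
         degenerate = doc$bounds$lower == doc$bounds$upper,
         feature_ids = fids),
    class = "normalization_bounds")
  n_bin <- as.integer(doc$n_bin)
  refs <- lapply(doc$references, function(ref) {
    H <- do.call(cbind, lapply(ref$histogram, as.numeric))
    colnames(H) <- unlist(ref$histogram_features)
    sums <- colSums(H)
    if (any(abs(sums - 1) > 1e-8)) {
      abort(sprintf("Module '%s': reference '%s' has a non-stochastic histogram column.",
                    path, ref$id))
    }
    R <- structure(H, class = c("distribution_matrix", "matrix"),
                   n_bin = n_bin,
                   in_range_counts = rep(NA_integer_, ncol(H)),
                   uniform_cols = rep(FALSE, ncol(H)))
    list(id = ref$id,
         R = R,
         P = reduction_matrix(unlist(ref$reduction), length(fids)),
         alpha = ref$alpha,
         diagonal_distance = ref$diagonal_distance,
         diagonal_ok = ref$diagonal_distance < ref$alpha)
  })
  ids <- vapply(refs, `[[`, "", "id")
  names(refs) <- ids
  D <- do.call(rbind, lapply(doc$D, as.numeric))
  dimnames(D) <- list(ids, ids)
  merge_groups <- if (length(doc$merge_groups) > 0) {
    lapply(doc$merge_groups, as.integer)
  } else NULL
  structure(
    list(references = refs, ref_ids = ids, bounds = bounds, n_bin = n_bin,
         distance_spec = distance_spec(doc$distance$omega,
                                       doc$distance$aggregator),
         params = params, beta = doc$beta, D = D,
         alpha = setNames(vapply(refs, `[[`, 0, "alpha"), ids),
         merge_groups = merge_groups,
         alerts = as.character(unlist(doc$alerts))),
    class = "qc_module")
}

#' Write a QC report stream as JSON lines
#'
#' One JSON object per report row (batch id, reference, compatibility,
#' quality components, signed distance, argmax feature).
#'
#' @param report A `qc_report` or `qc_stream` tibble.
#' @param path Output `.jsonl` file.
#' @return `path`, invisibly.
#' @export
write_qc_report_jsonl <- function(report, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in seq_len(nrow(report))) {
    writeLines(jsonlite::toJSON(as.list(report[r, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Write a QC report stream as a flat CSV
#'
#' @param report A `qc_report` or `qc_stream` tibble.
#' @param path Output `.csv` file.
#' @return `path`, invisibly.
#' @export
write_qc_report_csv <- function(report, path) {
  readr::write_csv(as_tibble(report), path)
  invisible(path)
}

#' Read a QC report stream written as JSON lines
#' @param path A `.jsonl` file from [write_qc_report_jsonl()].
#' @return A tibble with one row per report line.
#' @export
read_qc_report_jsonl <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(ln) {
    as_tibble(jsonlite::fromJSON(ln))
  }))
}
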