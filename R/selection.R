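# Composable nuclei selection methods.
#
# A pipeline representation is only as good as the nuclei that feed it.
# Three base selection methods can be composed: an elliptic interior
# filter that avoids the dense clusters at the slide edges, a spatially
# stratified sampler that avoids oversampling clusters, and a debris
# filter. Composition order is debris -> interior -> sampling, so that
# sampling quotas are met from eligible nuclei only.

#' Selection specification for nuclei extraction
#'
#' Bundles the composable selection methods and the total nucleus budget
#' used by [extract_feature_matrix()].
#'
#' @param n_nuc Total number of nuclei to extract across the batch; each
#'   WSI contributes a quota of `floor(n_nuc / n_wsi)`.
#' @param intern_tau Either `NA` (filter absent) or a fraction in
#'   `(0, 1]`: nuclei are kept only inside the centered ellipse with full
#'   axes `tau * width` and `tau * height`.
#' @param use_distrib If `TRUE`, the per-WSI quota is drawn by spatially
#'   stratified sampling ([select_distrib()]); otherwise by uniform
#'   random sampling.
#' @param use_debris If `TRUE`, rows flagged as debris are removed first.
#' @param seed Integer seed governing all sampling.
#'
#' @return A `selection_spec` object.
#' @export
selection_spec <- function(n_nuc, intern_tau = NA, use_distrib = FALSE,
                           use_debris = FALSE, seed = 1L) {
  assert_count(n_nuc, "n_nuc")
  if (!is.na(intern_tau) && (intern_tau <= 0 || intern_tau > 1)) {
    abort("`intern_tau` must be NA (absent) or in (0, 1].")
  }
  structure(
    list(n_nuc = as.integer(n_nuc),
         intern_tau = as.numeric(intern_tau),
         use_distrib = isTRUE(use_distrib),
         use_debris = isTRUE(use_debris),
         seed = as.integer(seed)),
    class = "selection_spec"
  )
}

#' Keep nuclei inside the centered ellipse
#'
#' Retains rows whose coordinates satisfy
#' `((x - W/2) / (tau W/2))^2 + ((y - H/2) / (tau H/2))^2 <= 1`, i.e. the
#' interior of the ellipse centered on the slide whose full axes are a
#' fraction `tau` of the slide width and height. Row order is preserved.
#' This avoids the dense nucleus clusters that centrifugation leaves at
#' the slide edges, where overlapping nuclei are poorly segmented.
#'
#' @param table A nuclei table with `x`, `y` columns.
#' @param tau Fraction in `(0, 1]`.
#' @param wsi_dims Width/height; taken from the table's attribute when
#'   omitted.
#' @return The filtered table.
#' @export
select_intern <- function(table, tau, wsi_dims = NULL) {
  if (!all(c("x", "y") %in% names(table))) {
    abort("`table` must carry `x` and `y` coordinates.")
  }
  if (tau <= 0 || tau > 1) abort("`tau` must be in (0, 1].")
  dims <- resolve_dims(table, wsi_dims)
  w <- dims[["width"]]; h <- dims[["height"]]
  a <- tau * w / 2; b <- tau * h / 2
  keep <- ((table$x - w / 2) / a)^2 + ((table$y - h / 2) / b)^2 <= 1
  restore_batch_attrs(table[keep, , drop = FALSE], table)
}

#' Spatially stratified nucleus sampling
#'
#' Extracts up to `target_n` evenly distributed nuclei: the slide is
#' tiled into a `g x g` grid with `g = ceiling(sqrt(target_n))`, the rows
#' of each occupied cell are shuffled, and cells are visited round-robin,
#' taking one nucleus per occupied cell per round until the target is
#' reached. This caps the contribution of any dense cluster at roughly
#' its share of occupied cells rather than its share of nuclei.
#'
#' @param table A nuclei table.
#' @param target_n Number of nuclei to draw (>= 1).
#' @param wsi_dims Width/height; taken from the table attribute when
#'   omitted.
#' @param seed Integer seed; the same seed reproduces the selection.
#' @return A table of `min(target_n, nrow(table))` rows (original row
#'   order). An empty input yields an empty result with a warning.
#' @export
select_distrib <- function(table, target_n, wsi_dims = NULL, seed = 1L) {
  assert_count(target_n, "target_n")
  if (nrow(table) == 0L) {
    warn("`select_distrib()` called on an empty table; returning it unchanged.")
    return(table)
  }
  dims <- resolve_dims(table, wsi_dims)
  g <- ceiling(sqrt(target_n))
  ix <- pmin(floor(table$x / dims[["width"]] * g), g - 1)
  iy <- pmin(floor(table$y / dims[["height"]] * g), g - 1)
  cell <- ix * g + iy
  by_cell <- split(seq_len(nrow(table)), cell)

  picked <- withr::with_seed(as.integer(seed), {
    shuffled <- lapply(by_cell, function(idx) {
      if (length(idx) > 1L) sample(idx) else idx
    })
    depth <- max(lengths(shuffled))
    order_mat <- unlist(lapply(seq_len(depth), function(r) {
      vapply(shuffled, function(v) if (length(v) >= r) v[r] else NA_integer_,
             integer(1))
    }))
    head(order_mat[!is.na(order_mat)], target_n)
  })
  restore_batch_attrs(table[sort(picked), , drop = FALSE], table)
}

#' Remove rows flagged as debris
#'
#' @param table A nuclei table with an `is_debris` column.
#' @return The table restricted to `is_debris == FALSE`; warns when
#'   nothing survives.
#' @export
select_debris <- function(table) {
  if (!"is_debris" %in% names(table)) {
    abort("`table` must carry an `is_debris` flag.")
  }
  out <- table[!table$is_debris, , drop = FALSE]
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warn("All rows are flagged as debris; returning an empty table.")
  }
  restore_batch_attrs(out, table)
}

#' Extract the nuclei feature matrix of a batch
#'
#' Applies, in order: the debris filter (if enabled), the elliptic
#' interior filter (if enabled), then per-WSI sampling of the quota
#' `floor(n_nuc / n_wsi)` — spatially stratified when `use_distrib` is
#' set, uniformly at random otherwise — and stacks the surviving rows'
#' feature vectors. With ample nuclei the result has exactly
#' `quota * n_wsi` rows; a WSI that cannot fill its quota contributes
#' what it has, with a shortfall warning.
#'
#' @param batch A `wsi_batch` (or nuclei tibble with batch attributes).
#' @param spec A [selection_spec()].
#' @return A numeric matrix of `n <= n_nuc` rows, columns named by
#'   feature identifier.
#' @export
extract_feature_matrix <- function(batch, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  if (nrow(batch) == 0L) abort("`batch` is empty.")
  fcols <- feature_cols(batch)
  if (length(fcols) == 0L) abort("`batch` carries no feature columns (f_...).")
  ids <- wsi_ids_in_order(batch)
  quota <- spec$n_nuc %/% length(ids)
  if (quota < 1L) {
    abort(sprintf("n_nuc = %d spread over %d WSIs leaves a per-WSI quota of 0.",
                  spec$n_nuc, length(ids)))
  }
  dims <- resolve_dims(batch, NULL)

  shortfall <- character(0)
  pieces <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tbl <- batch[batch$wsi_id == ids[k], , drop = FALSE]
    tbl <- restore_batch_attrs(tbl, batch)
    if (spec$use_debris) {
      tbl <- suppressWarnings(select_debris(tbl))
    }
    if (!is.na(spec$intern_tau)) {
      tbl <- select_intern(tbl, spec$intern_tau, dims)
    }
    if (nrow(tbl) == 0L) {
      shortfall <- c(shortfall, ids[k])
      next
    }
    wsi_seed <- derive_seed(spec$seed, k)
    if (spec$use_distrib) {
      tbl <- select_distrib(tbl, quota, dims, seed = wsi_seed)
    } else if (nrow(tbl) > quota) {
      keep <- withr::with_seed(wsi_seed, sample(nrow(tbl), quota))
      tbl <- tbl[sort(keep), , drop = FALSE]
    }
    if (nrow(tbl) < quota) shortfall <- c(shortfall, ids[k])
    pieces[[k]] <- as.matrix(tbl[, fcols, drop = FALSE])
  }
  if (length(shortfall) > 0L) {
    warn(sprintf(
      "Quota shortfall: %d WSI(s) contributed fewer than %d eligible nuclei (%s).",
      length(shortfall), quota,
      paste(head(shortfall, 5), collapse = ", ")))
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    abort("No eligible nuclei survived selection in any WSI.")
  }
  storage.mode(out) <- "double"
  out
}
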