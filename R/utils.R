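# Internal helpers shared across modules.

# Feature columns follow the fixed naming f_000, f_001, ... so that a
# nuclei table is self-describing: everything else (wsi_id, x, y,
# is_debris) is metadata.
feature_ids <- function(n_feat) sprintf("f_%03d", seq_len(n_feat) - 1L)

feature_cols <- function(df) grep("^f_\\d+$", names(df), value = TRUE)

# Derive a secondary seed from a base seed; kept below 2^31 - 1 so it is
# always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 97651L) * 21221 + (k %% 65213L) * 31 + 7L)
}

# QC alerts are signalled as classed warnings so callers (and the CLI)
# can react without aborting the computation that produced them.
qc_alert <- function(message, code) {
  warn(message, class = "slideqc_alert", code = code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, deparse(x)))
  }
  invisible(as.integer(x))
}

# Extract WSI dimensions from an explicit argument or a table attribute.
resolve_dims <- function(table, wsi_dims) {
  dims <- wsi_dims %||% attr(table, "wsi_dims")
  if (is.null(dims)) {
    abort("WSI dimensions are required: pass `wsi_dims` or use a table created by `generate_batch()`/`read_nuclei_tables()`.")
  }
  dims <- as.numeric(dims)
  if (length(dims) != 2L || any(!is.finite(dims)) || any(dims <= 0)) {
    abort("`wsi_dims` must be two positive numbers (width, height).")
  }
  names(dims) <- c("width", "height")
  dims
}

# Re-attach batch metadata after a dplyr verb stripped it.
restore_batch_attrs <- function(new, old) {
  attr(new, "pipeline_id") <- attr(old, "pipeline_id")
  attr(new, "wsi_dims") <- attr(old, "wsi_dims")
  class(new) <- unique(c("wsi_batch", class(new)))
  new
}

wsi_ids_in_order <- function(batch) unique(as.character(batch$wsi_id))

n_wsi_of <- function(batch) length(wsi_ids_in_order(batch))

# First `n_wsi` WSIs of a batch, in order of appearance.
batch_head <- function(batch, n_wsi) {
  ids <- wsi_ids_in_order(batch)
  if (length(ids) < n_wsi) {
    abort(sprintf("Batch has %d WSIs but %d were requested.",
                  length(ids), n_wsi))
  }
  keep <- batch$wsi_id %in% ids[seq_len(n_wsi)]
  restore_batch_attrs(batch[keep, , drop = FALSE], batch)
}
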