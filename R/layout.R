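#' Construct a field layout for a rectangular planting grid
#'
#' Builds the plant-position table for a field trial planted on a regular grid,
#' mirroring a typical single-genotype maize trial: rows of closely spaced
#' plants (default 10 cm apart within a row), rows themselves further apart
#' (default 75 cm). Each plant receives binary labels for sequencing batch,
#' day of harvest (DOH) and SNP subgroup, coded 0 for the largest group and 1
#' for the smallest, as is conventional for reference-coded fixed effects.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param within_row_spacing distance in cm between neighbouring plants within
#'   a row (maps to the x coordinate).
#' @param between_row_spacing distance in cm between rows (y coordinate).
#' @param batch_fraction,doh_fraction,snp_fraction fraction of plants in the
#'   minority (code 1) group for each label; must be < 0.5 so that code 0 is
#'   the majority.
#' @param scheme label assignment scheme: `"block"` assigns batch by a column
#'   block and DOH by a row block (contiguous field blocks, as harvesting and
#'   library preparation happen in batches), SNP labels at random; `"random"`
#'   assigns all three at random.
#' @param seed integer seed for the random label assignments.
#' @return a `data.frame` of class `field_layout` with columns `plant_id`,
#'   `row`, `col`, `x_cm`, `y_cm`, `batch`, `doh`, `snp_group`.
#' @examples
#' layout <- make_field_layout(10, 56)
#' max(layout$x_cm)  # 550 cm: (56 - 1) * 10
#' @export
make_field_layout <- function(n_rows = 10L, n_cols = 56L,
                              within_row_spacing = 10, between_row_spacing = 75,
                              batch_fraction = 0.2, doh_fraction = 0.4,
                              snp_fraction = 0.3,
                              scheme = c("block", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop("invalid config: grid dimensions must be positive integers")
  if (within_row_spacing <= 0 || between_row_spacing <= 0)
    stop("invalid config: spacings must be positive")
  for (f in c(batch_fraction, doh_fraction, snp_fraction))
    if (f < 0 || f >= 0.5) stop("invalid config: minority fractions must lie in [0, 0.5)")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  n <- nrow(grid)
  layout <- data.frame(
    plant_id = sprintf("plant_%03d", seq_len(n)),
    row = grid$row, col = grid$col,
    x_cm = grid$col * within_row_spacing,
    y_cm = grid$row * between_row_spacing,
    stringsAsFactors = FALSE
  )
  n_minor <- function(frac) max(0L, min(n - 1L, as.integer(round(frac * n))))
  set.seed(child_seed(seed, 1L))
  if (scheme == "block") {
    # batch: last columns of the field; doh: last rows. Mimics border-block
    # harvesting/library batches.
    nb <- n_minor(batch_fraction)
    layout$batch <- as.integer(rank(-layout$col, ties.method = "first") <= nb)
    nd <- n_minor(doh_fraction)
    layout$doh <- as.integer(rank(-(layout$row * n_cols + layout$col),
                                  ties.method = "first") <= nd)
  } else {
    layout$batch <- as.integer(seq_len(n) %in% sample.int(n, n_minor(batch_fraction)))
    layout$doh <- as.integer(seq_len(n) %in% sample.int(n, n_minor(doh_fraction)))
  }
  layout$snp_group <- as.integer(seq_len(n) %in% sample.int(n, n_minor(snp_fraction)))
  class(layout) <- c("field_layout", "data.frame")
  layout
}

#' Pairwise Euclidean distances between plants
#'
#' @param layout a `field_layout`.
#' @return a dense symmetric matrix of distances in cm.
#' @export
field_distances <- function(layout) {
  stopifnot(is.data.frame(layout), all(c("x_cm", "y_cm") %in% names(layout)))
  d <- as.matrix(stats::dist(cbind(layout$x_cm, layout$y_cm)))
  dimnames(d) <- list(layout$plant_id, layout$plant_id)
  d
}

#' Read / write a field layout as TSV
#' @param path file path.
#' @rdname layout_io
#' @export
read_field_layout <- function(path) {
  layout <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  needed <- c("plant_id", "row", "col", "x_cm", "y_cm", "batch", "doh", "snp_group")
  missing <- setdiff(needed, names(layout))
  if (length(missing))
    stop("layout file misses column(s): ", paste(missing, collapse = ", "))
  class(layout) <- c("field_layout", "data.frame")
  layout
}

#' @param layout a `field_layout`.
#' @rdname layout_io
#' @export
write_field_layout <- function(layout, path) {
  utils::write.table(as.data.frame(layout), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
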