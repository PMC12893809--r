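# Minimal in-memory raster and the multi-scale predictor operations.
#
# Conventions: `origin` is the north-west corner; row 1 is the northernmost
# row; cells are half-open [x, x + cell) x (y - cell, y]; cell centres sit at
# origin + (col - 1/2) * cell east and origin - (row - 1/2) * cell south.
# Values are stored as a plain numeric matrix with NA as nodata.  Rasters are
# (de)serialised as ESRI ASCII grids - a plain-text format readable by any
# GIS - since no binary GeoTIFF codec is assumed.

#' Construct a raster
#'
#' @param values Numeric matrix (row 1 = north).  Categorical rasters carry
#'   integer class codes.
#' @param origin Length-2 numeric, north-west corner `(x, y)` in metres.
#' @param cell Cell size in metres.
#' @param kind `"continuous"` or `"categorical"`.
#' @return Object of class `uraster`.
#' @export
new_raster <- function(values, origin, cell, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(cell > 0, length(origin) == 2)
  if (kind == "categorical" && any(values[!is.na(values)] %% 1 != 0))
    stop("categorical raster requires integer codes")
  structure(list(values = values, origin = as.numeric(origin), cell = cell,
                 n_rows = nrow(values), n_cols = ncol(values), kind = kind),
            class = "uraster")
}

#' @export
print.uraster <- function(x, ...) {
  cat(sprintf("<uraster %s> %d x %d cells @ %g m, NW corner (%.1f, %.1f)\n",
              x$kind, x$n_rows, x$n_cols, x$cell, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Coordinates of all cell centres
#' @param r A `uraster`.
#' @return List with vectors `x` (by column) and `y` (by row).
#' @export
cell_centres <- function(r) {
  list(x = r$origin[1] + (seq_len(r$n_cols) - 0.5) * r$cell,
       y = r$origin[2] - (seq_len(r$n_rows) - 0.5) * r$cell)
}

#' Value of the cell containing each point (NA outside the grid)
#' @param r A `uraster`.
#' @param px,py Point coordinates, metres.
#' @export
raster_value_at <- function(r, px, py) {
  col <- floor((px - r$origin[1]) / r$cell) + 1
  row <- floor((r$origin[2] - py) / r$cell) + 1
  ok <- col >= 1 & col <= r$n_cols & row >= 1 & row <= r$n_rows
  out <- rep(NA_real_, length(px))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write / read a raster as an ESRI ASCII grid (plain text)
#'
#' @param r A `uraster`.
#' @param path File path (conventionally `.asc`).
#' @param digits Significant digits written.
#' @export
write_asc <- function(r, path, digits = 8) {
  hdr <- c(sprintf("ncols %d", r$n_cols),
           sprintf("nrows %d", r$n_rows),
           sprintf("xllcorner %.6f", r$origin[1]),
           sprintf("yllcorner %.6f", r$origin[2] - r$n_rows * r$cell),
           sprintf("cellsize %.6f", r$cell),
           "NODATA_value -9999")
  v <- r$values
  v[is.na(v)] <- -9999
  lines <- apply(v, 1, function(row) paste(signif(row, digits), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_asc
#' @param kind Raster kind to tag on read.
#' @export
read_asc <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) as.numeric(sub(paste0("^", key, "\\s+"), "",
                                      hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]))
  ncols <- val("ncols"); nrows <- val("nrows")
  xll <- val("xllcorner"); yll <- val("yllcorner"); cs <- val("cellsize")
  nd <- val("NODATA_value")
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == nd] <- NA
  new_raster(m, origin = c(xll, yll + nrows * cs), cell = cs, kind = kind)
}

# Per-axis overlap-length matrix between source cells (size cs, n of them)
# and target cells (size ct, m of them) sharing the same starting edge.
.overlap_weights <- function(n_src, cs, n_tgt, ct) {
  W <- matrix(0, n_tgt, n_src)
  for (k in seq_len(n_tgt)) {
    lo <- (k - 1) * ct; hi <- k * ct
    j0 <- max(1L, floor(lo / cs) + 1L)
    j1 <- min(n_src, ceiling(hi / cs))
    if (j0 > j1) next
    j <- j0:j1
    W[k, j] <- pmax(0, pmin(j * cs, hi) - pmax((j - 1) * cs, lo))
  }
  W
}

#' Resample a raster to a new resolution
#'
#' Continuous rasters are aggregated by area-weighted block means; categorical
#' rasters by area-weighted majority vote with ties resolved to the lowest
#' code.  The north-west corner is preserved; the target grid spans at least
#' the source extent.
#'
#' @param r A `uraster`.
#' @param target_cell Target cell size, metres (default 50).
#' @return Resampled `uraster`.
#' @export
resample_raster <- function(r, target_cell = 50) {
  stopifnot(inherits(r, "uraster"), target_cell > 0)
  if (r$n_rows == 0 || r$n_cols == 0) stop("empty raster")
  if (target_cell == r$cell) return(r)
  n_tr <- ceiling(r$n_rows * r$cell / target_cell)
  n_tc <- ceiling(r$n_cols * r$cell / target_cell)
  Wy <- .overlap_weights(r$n_rows, r$cell, n_tr, target_cell)
  Wx <- .overlap_weights(r$n_cols, r$cell, n_tc, target_cell)
  M <- !is.na(r$values)
  V0 <- r$values; V0[!M] <- 0
  if (r$kind == "continuous") {
    num <- Wy %*% V0 %*% t(Wx)
    den <- Wy %*% (M + 0) %*% t(Wx)
    out <- num / den
    out[den <= 0] <- NA
  } else {
    codes <- sort(unique(r$values[M]))
    best <- matrix(-Inf, n_tr, n_tc)
    out <- matrix(NA_real_, n_tr, n_tc)
    for (cd in codes) { # ascending: later codes must strictly beat -> lowest wins ties
      w <- Wy %*% ((M & r$values == cd) + 0) %*% t(Wx)
      sel <- w > best
      out[sel] <- cd
      best[sel] <- w[sel]
    }
    out[best <= 0] <- NA
  }
  new_raster(out, origin = r$origin, cell = target_cell, kind = r$kind)
}

#' Mean raster value within a circular neighbourhood
#'
#' Averages the cells whose centres lie within `radius` metres of `centre`
#' (nodata excluded).  Errors when the circle covers no cell centre.
#'
#' @param r A `uraster`.
#' @param centre Length-2 numeric `(x, y)`.
#' @param radius Radius in metres (the analysis scales are 50, 200, 1000).
#' @export
focal_mean <- function(r, centre, radius) {
  stopifnot(inherits(r, "uraster"), radius > 0)
  cc <- cell_centres(r)
  dx2 <- (cc$x - centre[1])^2
  dy2 <- (cc$y - centre[2])^2
  sel_c <- which(dx2 <= radius^2)
  sel_r <- which(dy2 <= radius^2)
  if (!length(sel_c) || !length(sel_r)) stop("no cell centres within radius")
  sub <- r$values[sel_r, sel_c, drop = FALSE]
  inside <- outer(dy2[sel_r], dx2[sel_c], `+`) <= radius^2
  vals <- sub[inside & !is.na(sub)]
  if (!length(vals)) stop("no cell centres within radius")
  mean(vals)
}

#' Greedy collinearity screen on a predictor table
#'
#' While any pair of columns has Pearson `|r|` above `threshold`, the pair
#' with the largest `|r|` (ties by column name) is examined and the member
#' with the lower performance score is dropped.  Scores default to the
#' univariate 5-fold cross-validated AUC of a single-variable maximum-entropy
#' model, which requires `is_presence`; precomputed scores can be supplied
#' instead.
#'
#' @param x data.frame of numeric candidate columns (rows = presence +
#'   background sites).
#' @param threshold Collinearity cut-off on `|r|`.
#' @param scores Optional named numeric vector of per-variable performance.
#' @param is_presence Logical vector marking presence rows (used only when
#'   `scores` is `NULL`).
#' @param seed Seed for the internal cross-validation folds.
#' @return Character vector of retained column names.
#' @export
collinearity_filter <- function(x, threshold = 0.7, scores = NULL,
                                is_presence = NULL, seed = 1) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 10)
  const <- vapply(x, function(v) stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v)),
                  logical(1))
  if (any(const)) {
    warning("dropping constant column(s): ", paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  vars <- sort(names(x))
  if (is.null(scores)) {
    if (is.null(is_presence))
      stop("either scores or is_presence must be supplied")
    scores <- vapply(vars, function(v)
      univariate_cv_auc(x[[v]], is_presence, seed = seed), numeric(1))
    names(scores) <- vars
  }
  keep <- vars
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(x[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    # deterministic: first pair in (row name, col name) alphabetical order
    pairs <- cbind(rownames(cm)[idx[, 1]], colnames(cm)[idx[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    a <- pairs[1, 1]; b <- pairs[1, 2]
    drop <- if (scores[[a]] < scores[[b]]) a else b
    keep <- setdiff(keep, drop)
  }
  keep
}
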