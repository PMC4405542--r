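# Neutral landscape generation: a stationary Gaussian random field with
# exponential spatial correlation, simulated by FFT circulant embedding and
# discretized into habitat codes by rank thresholding so that requested
# habitat proportions are met exactly up to integer pixel counts.

#' Simulate a categorical habitat landscape
#'
#' Draws a zero-mean, unit-variance Gaussian field with correlation
#' exp(-d / corr_range) on a rows x cols grid (circulant embedding on the
#' doubled torus; the few negative embedding eigenvalues of the exponential
#' kernel are clipped to zero, the standard approximation). The field is
#' then cut at its empirical quantiles: the lowest \code{proportions[1]}
#' fraction of pixels becomes habitat 1, the next fraction habitat 2, the
#' rest habitat 3. \code{corr_range = 0} gives spatially independent noise.
#'
#' @param rows,cols grid dimensions in pixels (pixel size 1 unit).
#' @param proportions three positive fractions summing to 1.
#' @param corr_range correlation range in pixels (e-folding distance).
#' @return a \code{landscape}: list with \code{grid} (integer matrix of
#'   codes 1..3, row 1 = north edge), \code{pixel_size}, \code{target}
#'   (continuous (x, y) of the center pixel, the long-term attractor),
#'   \code{proportions}, \code{corr_range} and a patch cache.
#' @export
simulate_landscape <- function(rows = 1024L, cols = 1024L,
                               proportions = c(0.8, 0.1, 0.1),
                               corr_range = 20) {
  if (rows * cols < 3L) stop("invalid-dimensions: grid too small", call. = FALSE)
  stopifnot(length(proportions) == 3L, all(proportions > 0),
            abs(sum(proportions) - 1) < 1e-8, corr_range >= 0)
  field <- if (corr_range == 0) {
    matrix(stats::rnorm(rows * cols), rows, cols)
  } else {
    .grf_circulant(rows, cols, corr_range)
  }
  n <- rows * cols
  r <- rank(field, ties.method = "first")
  cut1 <- round(n * proportions[1])
  cut2 <- round(n * (proportions[1] + proportions[2]))
  grid <- matrix(1L + (r > cut1) + (r > cut2), rows, cols)
  center <- c(ceiling(cols / 2) - 0.5, rows - ceiling(rows / 2) + 0.5)
  structure(list(grid = grid, pixel_size = 1, target = center,
                 proportions = proportions, corr_range = corr_range,
                 cache = new.env(parent = emptyenv())),
            class = "landscape")
}

# Stationary GRF via circulant embedding on the (2 rows) x (2 cols) torus.
.grf_circulant <- function(rows, cols, range) {
  m <- 2L * rows; k <- 2L * cols
  di <- pmin(0:(m - 1L), m - 0:(m - 1L))
  dj <- pmin(0:(k - 1L), k - 0:(k - 1L))
  dist <- sqrt(outer(di^2, dj^2, "+"))
  lam <- Re(stats::fft(exp(-dist / range)))
  lam[lam < 0] <- 0                       # clip tiny negative eigenvalues
  e <- matrix(complex(real = stats::rnorm(m * k),
                      imaginary = stats::rnorm(m * k)), m, k)
  f <- stats::fft(sqrt(lam) * e) / sqrt(m * k)
  Re(f)[seq_len(rows), seq_len(cols)]
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d pixels, habitat proportions %s, range %g\n",
              nrow(x$grid), ncol(x$grid),
              paste(round(x$proportions, 3), collapse = "/"), x$corr_range))
  invisible(x)
}

#' Write a landscape as a plain-text integer grid
#'
#' Three header lines (rows, cols, pixel size) followed by one line of
#' space-separated habitat codes per grid row, row 1 (north edge) first.
#'
#' @param landscape a \code{landscape}.
#' @param path output file.
#' @export
write_landscape <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("rows", nrow(landscape$grid)),
               paste("cols", ncol(landscape$grid)),
               paste("pixel_size", landscape$pixel_size)), con)
  utils::write.table(landscape$grid, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a landscape written by \code{\link{write_landscape}}
#'
#' @param path file path.
#' @return a \code{landscape} (proportions recomputed from the grid;
#'   correlation range unknown, NA).
#' @export
read_landscape <- function(path) {
  hdr <- readLines(path, n = 3L)
  kv <- do.call(rbind, strsplit(hdr, " "))
  rows <- as.integer(kv[kv[, 1] == "rows", 2])
  cols <- as.integer(kv[kv[, 1] == "cols", 2])
  ps <- as.numeric(kv[kv[, 1] == "pixel_size", 2])
  grid <- as.matrix(utils::read.table(path, skip = 3L,
                                      colClasses = "integer"))
  dimnames(grid) <- NULL
  if (nrow(grid) != rows || ncol(grid) != cols)
    stop("landscape file dimensions disagree with header", call. = FALSE)
  props <- as.vector(table(factor(grid, levels = 1:3))) / (rows * cols)
  center <- c(ceiling(cols / 2) - 0.5, rows - ceiling(rows / 2) + 0.5) * ps
  structure(list(grid = grid, pixel_size = ps, target = center,
                 proportions = props, corr_range = NA_real_,
                 cache = new.env(parent = emptyenv())),
            class = "landscape")
}

# Continuous center coordinates of one habitat's pixels, cached on the
# landscape (the discrete-choice walker queries them every step).
.habitat_pixels <- function(landscape, habitat) {
  key <- paste0("h", habitat)
  if (!is.null(landscape$cache[[key]])) return(landscape$cache[[key]])
  g <- landscape$grid
  nr <- nrow(g)
  idx <- which(g == habitat)               # column-major linear indices
  if (length(idx) == 0L)
    stop("landscape has no habitat-", habitat, " pixels", call. = FALSE)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  ctr <- pixel_center(ri, ci, nr, landscape$pixel_size)
  out <- list(px = ctr[, "x"], py = ctr[, "y"])
  landscape$cache[[key]] <- out
  out
}
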