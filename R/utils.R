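#' Well identifiers for a rectangular plate
#'
#' Letter-number well labels in row-major order, e.g. `A01 ... P24` for a
#' 384-well plate. Supported formats are 24 (4x6), 96 (8x12), 384 (16x24)
#' and 1536 (32x48) wells.
#'
#' @param n_wells Total number of wells on the plate.
#' @return Character vector of length `n_wells`.
#' @export
#' @examples
#' head(well_names(384))
well_names <- function(n_wells) {
  dims <- switch(as.character(n_wells),
    "24"   = c(4L, 6L),
    "96"   = c(8L, 12L),
    "384"  = c(16L, 24L),
    "1536" = c(32L, 48L),
    stop("unsupported plate format: ", n_wells, " wells", call. = FALSE)
  )
  rows <- if (dims[1L] <= 26L) LETTERS[seq_len(dims[1L])] else
    c(LETTERS, paste0("A", LETTERS))[seq_len(dims[1L])]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(dims[2L])), paste0)))
}

#' Standard deviation of the median of n standard normal draws
#'
#' Used to calibrate effect sizes: the robust spread of per-well medians
#' (and of replicate-aggregated profiles) scales with this factor relative
#' to the underlying per-site noise. Exact (numerical integration) for odd
#' n; for even n the order-statistic density of the midpoint average has no
#' simple closed form and the asymptotic value sqrt(pi / (2 n)) is used.
#'
#' @param n Number of draws the median is taken over.
#' @return Positive scalar, the SD of the sample median.
#' @export
#' @examples
#' median_sd_factor(9)   # ~0.407
#' median_sd_factor(3)   # ~0.669
median_sd_factor <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == as.integer(n))
  n <- as.integer(n)
  if (n == 1L) return(1)
  if (n %% 2L == 1L) {
    m <- (n - 1L) %/% 2L
    dens <- function(x) {
      exp(lgamma(n + 1) - 2 * lgamma(m + 1) +
            m * (pnorm(x, log.p = TRUE) +
                   pnorm(x, lower.tail = FALSE, log.p = TRUE)) +
            dnorm(x, log = TRUE))
    }
    v <- integrate(function(x) x^2 * dens(x), -Inf, Inf,
                   rel.tol = 1e-10)$value
    sqrt(v)
  } else {
    sqrt(pi / (2 * n))
  }
}

# consistent MAD-based robust scale (1.4826 * MAD); falls back to SD when
# method = "sd"
robust_scale <- function(x, method = c("mad", "sd")) {
  method <- match.arg(method)
  if (method == "mad") mad(x, na.rm = TRUE) else sd(x, na.rm = TRUE)
}

# column-wise median of a numeric matrix, NA-tolerant, without per-column
# R-level dispatch overhead for the all-finite fast path
col_medians <- function(x) {
  if (anyNA(x)) {
    apply(x, 2L, median, na.rm = TRUE)
  } else if (nrow(x) == 1L) {
    x[1L, ]
  } else {
    apply(x, 2L, median)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
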