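## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stage- and object-local random streams are derived deterministically from
#' one master integer seed plus a character label, so that adding a stage
#' never perturbs the stream of another. The result always fits in a 32-bit
#' signed integer.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 2147483647
  s <- (as.numeric(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483647)
}

with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

## Exact anisotropic Euclidean distance transform.
##
## Distance (in physical units) from every grid point to the nearest TRUE
## site, measured center-to-center with per-axis spacing. Computed by
## sequential 1D lower-envelope passes, which is exact for the squared
## Euclidean metric.
edt_distance <- function(sites, spacing) {
  d <- dim(sites)
  if (is.null(d)) stopf("edt_distance: `sites` must be a matrix or array")
  nd <- length(d)
  if (length(spacing) != nd)
    stopf("edt_distance: spacing must have one entry per dimension")
  if (!any(sites)) {
    out <- array(Inf, d)
    return(out)
  }
  f <- array(ifelse(sites, 0, Inf), d)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    fp <- aperm(f, perm)
    dm <- dim(fp)
    m <- .dt1d_cols(matrix(fp, nrow = dm[1]), spacing[ax])
    fp <- array(m, dm)
    f <- aperm(fp, order(perm))
  }
  sqrt(f)
}
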