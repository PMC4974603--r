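# Windowed r^2 LD pruning (the indep-pairwise style preprocessing step):
# in sliding windows of `window_size` markers, advanced by `step`, the
# later-indexed member of any pair with genotypic r^2 above the threshold is
# removed; window scans repeat until no window removes a marker.

#' Pruning parameters
#'
#' Defaults match the conventional preprocessing: windows of 200 markers
#' slid by 25, removing one of any pair with r^2 > 0.4.
#'
#' @param window_size window width in markers.
#' @param step window slide in markers (`step <= window_size`).
#' @param r2_threshold squared-correlation threshold in (0, 1].
#' @return a list with class `prune_params`.
#' @export
prune_params <- function(window_size = 200L, step = 25L,
                         r2_threshold = 0.4) {
  if (step > window_size) stop("step must be <= window_size")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 r2_threshold = as.numeric(r2_threshold)),
            class = "prune_params")
}

#' Genotypic r-squared between two dosage vectors
#'
#' Squared Pearson correlation of unphased dosages over pairwise-complete
#' observations (the composite-LD convention). Returns `NA` when fewer than
#' two complete pairs remain or either vector has zero variance over them
#' (undefined r^2 is *not* treated as high LD by [ld_prune()]).
#'
#' @param x,y equal-length numeric dosage vectors (may contain `NA`).
#' @return the squared correlation, or `NA_real_` if undefined.
#' @export
genotype_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# One pruning pass over the currently kept markers of one chromosome.
# `kept` holds column indices into `dos`; returns the surviving subset.
prune_pass <- function(dos, kept, params) {
  w <- params$window_size; s <- params$step; thr <- params$r2_threshold
  alive <- rep(TRUE, length(kept))
  starts <- seq(1L, max(1L, length(kept)), by = s)
  for (st in starts) {
    en <- min(st + w - 1L, length(kept))
    if (en <= st) next
    idx <- st:en
    sub <- dos[, kept[idx], drop = FALSE]
    r2 <- suppressWarnings(stats::cor(sub,
                                      use = "pairwise.complete.obs"))^2
    for (i in seq_along(idx)) {
      if (!alive[idx[i]]) next
      for (j in seq_along(idx)) {
        if (j <= i || !alive[idx[j]]) next
        v <- r2[i, j]
        if (!is.na(v) && v > thr) alive[idx[j]] <- FALSE
      }
    }
  }
  kept[alive]
}

#' LD-prune a genotype matrix
#'
#' Scans sliding windows within each chromosome (windows never span
#' chromosomes); within a window, pairs are examined in marker-index order
#' and the later-indexed member of any pair with `r^2 > r2_threshold` is
#' removed. Windows are re-scanned to convergence: the scan repeats until no
#' window removes a marker. Monomorphic markers (undefined r^2) are kept.
#'
#' @param G a [genotype_matrix()] with markers sorted by chromosome and
#'   position.
#' @param params a [prune_params()].
#' @param verbose log before/after marker counts (default FALSE).
#' @return sorted integer vector of surviving marker indices into
#'   `G$markers`.
#' @export
ld_prune <- function(G, params = prune_params(), verbose = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(params, "prune_params"))
  L <- nrow(G$markers)
  if (L == 0L) return(integer())
  dos <- G$dosages
  out <- integer()
  for (chr in unique(G$markers$chromosome)) {
    kept <- which(G$markers$chromosome == chr)
    repeat {
      nxt <- prune_pass(dos, kept, params)
      if (length(nxt) == length(kept)) break
      kept <- nxt
    }
    out <- c(out, kept)
  }
  out <- sort(out)
  if (verbose)
    message("ld_prune: ", L, " -> ", length(out), " markers (window ",
            params$window_size, ", step ", params$step, ", r2 > ",
            params$r2_threshold, " removed)")
  out
}
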