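# Core containers shared by all stages: marker metadata, the genotype matrix
# (unphased dosages of a counted allele), and per-sample metadata.

#' Construct a marker-information table
#'
#' Marker metadata mirrors a PLINK `.map` file plus the two observed alleles.
#' `allele_a` is the counted allele: dosages elsewhere in the package count
#' copies of `allele_a`.
#'
#' @param chromosome chromosome identifiers (coerced to character).
#' @param position 1-based physical positions in base pairs.
#' @param marker_id unique marker identifiers.
#' @param allele_a,allele_b single-character alleles, `allele_a != allele_b`
#'   per marker.
#' @return a `data.frame` with class `marker_info`.
#' @export
marker_info <- function(chromosome, position, marker_id, allele_a, allele_b) {
  df <- data.frame(chromosome = as.character(chromosome),
                   position = as.integer(position),
                   marker_id = as.character(marker_id),
                   allele_a = as.character(allele_a),
                   allele_b = as.character(allele_b),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$marker_id))
    stop("duplicate marker ids: ",
         paste(unique(df$marker_id[duplicated(df$marker_id)]), collapse = ", "))
  if (any(df$allele_a == df$allele_b))
    stop("allele_a must differ from allele_b for every marker")
  for (chr in unique(df$chromosome)) {
    pos <- df$position[df$chromosome == chr]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  class(df) <- c("marker_info", "data.frame")
  df
}

#' Construct a genotype matrix
#'
#' The common currency of the package: an `n` samples by `L` markers matrix of
#' unphased allele dosages in `{0, 1, 2}` (`NA` = missing), counting copies of
#' each marker's `allele_a`.
#'
#' @param dosages integer matrix, samples in rows, markers in columns.
#' @param samples character vector of unique sample identifiers (row order).
#' @param markers a [marker_info()] table (column order).
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `samples`, `markers`.
#' @export
genotype_matrix <- function(dosages, samples, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!inherits(markers, "marker_info"))
    markers <- marker_info(markers$chromosome, markers$position,
                           markers$marker_id, markers$allele_a,
                           markers$allele_b)
  if (nrow(dosages) != length(samples))
    stop("dosage rows (", nrow(dosages), ") != number of samples (",
         length(samples), ")")
  if (ncol(dosages) != nrow(markers))
    stop("dosage columns (", ncol(dosages), ") != number of markers (",
         nrow(markers), ")")
  if (anyDuplicated(samples))
    stop("duplicate sample ids")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must lie in {0, 1, 2} or be NA")
  dimnames(dosages) <- list(as.character(samples), markers$marker_id)
  structure(list(dosages = dosages, samples = as.character(samples),
                 markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$markers), " markers\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.3g; chromosomes: %s\n", miss,
              paste(unique(x$markers$chromosome), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or marker index
#'
#' @param x a [genotype_matrix()].
#' @param samples integer/logical/character index over samples (optional).
#' @param markers integer/logical index over markers (optional).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$samples) else samples
  mi <- if (is.null(markers)) seq_len(nrow(x$markers)) else markers
  mk <- x$markers[mi, , drop = FALSE]
  class(mk) <- c("marker_info", "data.frame")
  genotype_matrix(x$dosages[si, mi, drop = FALSE], x$samples[si], mk)
}

#' Construct a per-sample metadata table
#'
#' Holds the sidecar information accompanying genotypes: sex, the binary
#' self-reported label driving descent rules, and a free-text population tag.
#'
#' @param sample_id unique sample identifiers.
#' @param sex `"male"`, `"female"`, or `"unknown"`.
#' @param label `"labeled"`, `"unlabeled"`, or `NA` (unlabeled samples are the
#'   generic stand-in for non-self-reporting individuals).
#' @param population optional population tag (default `""`).
#' @return a `data.frame` with class `sample_meta`.
#' @export
sample_meta <- function(sample_id, sex, label, population = "") {
  sex <- as.character(sex)
  label <- as.character(label)
  if (!all(sex %in% c("male", "female", "unknown")))
    stop("sex must be 'male', 'female' or 'unknown'")
  if (!all(is.na(label) | label %in% c("labeled", "unlabeled")))
    stop("label must be 'labeled', 'unlabeled' or NA")
  df <- data.frame(sample_id = as.character(sample_id), sex = sex,
                   label = label,
                   population = rep_len(as.character(population),
                                        length(sample_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  class(df) <- c("sample_meta", "data.frame")
  df
}
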