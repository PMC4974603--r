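# Blinding and scoring: the release cohort is shuffled under a seeded
# permutation and re-identified with sequential anonymized ids; genotypes
# are untouched. Predictions are scored against the hidden key per rule.

#' Blind a simulated cohort for release
#'
#' Selects the release cohort (terminal offspring by default), applies a
#' seeded id permutation with sequential anonymized ids, strips sex,
#' pedigree links and labels from the public data, and builds the private
#' answer key. Genotypes are unmodified: the public dosage matrix differs
#' from the original only by row permutation and relabeling.
#'
#' @param ped a labeled, phased [pedigree()].
#' @param seed integer root seed (substream `"blind"`).
#' @param mode `"terminal_only"` (default) or `"all_generations"`.
#' @param rule [descent_rule()] for the grandparent column of the key.
#' @param retain_sex keep true sexes in the public metadata (default FALSE;
#'   sex is written as unknown/0).
#' @param anonymize_markers replace marker ids with sequential `snp000001..`
#'   ids (default FALSE, original ids kept).
#' @return a list with class `benchmark_bundle`:
#'   `genotypes` (blinded [genotype_matrix()]), `meta` (public
#'   [sample_meta()]), `manifest` (marker/sample counts and a seed hash),
#'   `blinding_map` (private data.frame `original_id`, `blinded_id`),
#'   `key` (private [answer_key()] on blinded ids).
#' @export
blind <- function(ped, seed = 1L, mode = c("terminal_only",
                                           "all_generations"),
                  rule = descent_rule("grandparent_threshold"),
                  retain_sex = FALSE, anonymize_markers = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  mode <- match.arg(mode)
  scope <- if (mode == "terminal_only") "terminal" else "all"
  key0 <- label_pedigree(ped, rule, scope = scope)
  ids <- key0$id
  n <- length(ids)

  perm <- with_seed(derive_seed(seed, "blind"), sample(n))
  blinded <- sprintf("B%04d", seq_len(n))
  # ids[perm[k]] becomes blinded[k]: release order is the permuted order
  map <- data.frame(original_id = ids[perm], blinded_id = blinded,
                    stringsAsFactors = FALSE)

  G <- pedigree_genotypes(ped, ids = map$original_id)
  Gb <- genotype_matrix(G$dosages, map$blinded_id, G$markers)
  if (anonymize_markers) {
    mk <- Gb$markers
    mk$marker_id <- sprintf("snp%06d", seq_len(nrow(mk)))
    Gb <- genotype_matrix(Gb$dosages, Gb$samples, mk)
  }
  sex_pub <- if (retain_sex)
    ped$individuals$sex[match(map$original_id, ped$individuals$id)]
  else rep("unknown", n)
  meta <- sample_meta(map$blinded_id, sex_pub, NA_character_, "blinded")

  key <- answer_key(map$blinded_id,
                    key0$halacha[match(map$original_id, key0$id)],
                    key0$law_of_return[match(map$original_id, key0$id)])
  manifest <- list(n_samples = n, n_markers = nrow(Gb$markers),
                   mode = mode,
                   seed_hash = derive_seed(seed, "blind_manifest"))
  structure(list(genotypes = Gb, meta = meta, manifest = manifest,
                 blinding_map = map, key = key),
            class = "benchmark_bundle")
}

#' Un-blind a bundle
#'
#' Restores original ids via the private blinding map (the inverse
#' permutation).
#'
#' @param bundle a `benchmark_bundle` from [blind()].
#' @return character vector: original id for each blinded sample, in the
#'   bundle's sample order.
#' @export
unblind_ids <- function(bundle) {
  stopifnot(inherits(bundle, "benchmark_bundle"))
  m <- bundle$blinding_map
  m$original_id[match(bundle$genotypes$samples, m$blinded_id)]
}

#' Score a label-prediction submission against the answer key
#'
#' Builds the confusion matrix over the ids present in the submission
#' (every submitted id must be in the key); key individuals without a
#' prediction are excluded and reported as `n_missing`.
#'
#' @param submission data.frame with columns `id` and `prediction`
#'   (logical or 0/1).
#' @param key an [answer_key()].
#' @param rule `"halacha"` or `"law_of_return"`: which key column to score
#'   against.
#' @return a list with class `score_report`: `rule`, `tp`, `fp`, `tn`,
#'   `fn`, `n_scored`, `n_missing`, `accuracy`, `sensitivity`,
#'   `specificity` (sensitivity/specificity are `NA` when undefined).
#' @export
score <- function(submission, key, rule = c("halacha", "law_of_return")) {
  stopifnot(inherits(key, "answer_key"))
  rule <- match.arg(rule)
  if (!all(c("id", "prediction") %in% names(submission)))
    stop("submission needs columns 'id' and 'prediction'")
  sub_id <- as.character(submission$id)
  unknown <- setdiff(sub_id, key$id)
  if (length(unknown))
    stop("submission contains id(s) not in the key: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(sub_id)) stop("duplicate ids in submission")
  pred <- as.logical(submission$prediction)
  truth <- key[[rule]][match(sub_id, key$id)]

  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  n <- length(pred)
  structure(list(rule = rule, tp = tp, fp = fp, tn = tn, fn = fn,
                 n_scored = n, n_missing = nrow(key) - n,
                 accuracy = if (n) (tp + tn) / n else NA_real_,
                 sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp) tn / (tn + fp) else NA_real_),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(
    "score_report [%s]: n=%d (missing %d)\n  accuracy %.3f  sensitivity %s  specificity %s\n  TP %d  FP %d  TN %d  FN %d\n",
    x$rule, x$n_scored, x$n_missing, x$accuracy,
    formatC(x$sensitivity, format = "f", digits = 3),
    formatC(x$specificity, format = "f", digits = 3),
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Write / read a submission TSV
#'
#' Two tab-separated columns with header: `id`, `prediction` (0/1).
#'
#' @param submission data.frame (`id`, `prediction`) for writing.
#' @param path file path.
#' @return `read_submission` returns a data.frame with logical predictions.
#' @export
write_submission <- function(submission, path) {
  out <- data.frame(id = submission$id,
                    prediction = as.integer(as.logical(submission$prediction)))
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_submission
#' @export
read_submission <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  data.frame(id = df$id, prediction = df$prediction == 1L,
             stringsAsFactors = FALSE)
}
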