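# PLINK text (.ped/.map) I/O, sidecar metadata TSV, answer keys (JSON),
# and TSV serialization of Q/F matrices and edge lists.
#
# Conventions (deliberate, documented):
#  * counted allele (allele_a) = first non-missing allele encountered per
#    marker in file order -- deterministic, needs no allele frequencies;
#  * "0" is the missing-allele code; a cell is missing if either allele is 0;
#  * markers whose missing rate exceeds `missing_cap` are dropped with a
#    warning.

PED_ALLELES <- c("A", "C", "G", "T", "1", "2", "0")

#' Read PLINK text genotypes
#'
#' Parses a whitespace-delimited `.ped`/`.map` pair into a
#' [genotype_matrix()] plus [sample_meta()]. Dosages count copies of the
#' first non-missing allele observed per marker in file order (the counted
#' allele); PLINK's minor-allele convention is not assumed.
#'
#' @param ped_path path to the `.ped` file (6 leading columns, then two
#'   allele columns per marker).
#' @param map_path path to the 4-column `.map` file.
#' @param missing_cap markers with missing rate above this are dropped with a
#'   warning (default 0.1).
#' @return a list with elements `genotypes` ([genotype_matrix()]) and
#'   `meta` ([sample_meta()]). Sex codes outside `{1, 2}` become `"unknown"`.
#' @export
read_plink_text <- function(ped_path, map_path, missing_cap = 0.1) {
  if (!file.exists(ped_path)) stop("no such .ped file: ", ped_path)
  if (!file.exists(map_path)) stop("no such .map file: ", map_path)

  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"),
                           col.names = c("chromosome", "marker_id",
                                         "cm", "position"))
  L <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  widths <- lengths(toks)
  expected <- 6L + 2L * L
  if (any(widths != expected)) {
    bad <- which(widths != expected)[1L]
    if (length(unique(widths)) > 1L)
      stop("ragged .ped: line ", bad, " has ", widths[bad],
           " fields, others differ")
    stop("marker count mismatch: .ped implies ", (widths[1L] - 6L) / 2,
         " markers but .map lists ", L)
  }
  n <- length(toks)
  tok <- matrix(unlist(toks), nrow = n, byrow = TRUE)

  iid <- tok[, 2L]
  sex_code <- tok[, 5L]
  sex <- ifelse(sex_code == "1", "male",
                ifelse(sex_code == "2", "female", "unknown"))
  if (any(sex == "unknown"))
    warning("sex code outside {1,2} for sample(s): ",
            paste(iid[sex == "unknown"], collapse = ", "),
            " (recorded as 'unknown')")

  a1 <- tok[, 6L + 2L * seq_len(L) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(L), drop = FALSE]
  bad_allele <- !(a1 %in% PED_ALLELES) | !(a2 %in% PED_ALLELES)
  if (any(bad_allele))
    stop("invalid allele code(s) in .ped: ",
         paste(unique(c(a1[bad_allele], a2[bad_allele])), collapse = ", "))

  counted <- character(L)
  other <- character(L)
  dos <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    obs <- c(rbind(a1[, j], a2[, j]))     # file order within the column
    obs <- obs[obs != "0"]
    if (length(obs) == 0L) {
      counted[j] <- "A"; other[j] <- "G"  # fully missing marker; placeholder
      next
    }
    counted[j] <- obs[1L]
    alt <- unique(obs[obs != obs[1L]])
    if (length(alt) > 1L)
      stop("marker ", map$marker_id[j], " has >2 alleles: ",
           paste(unique(obs), collapse = ", "))
    other[j] <- if (length(alt)) alt else
      setdiff(c("A", "C", "G", "T", "1", "2"), counted[j])[1L]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
    dos[miss, j] <- NA_integer_
  }

  mk <- marker_info(map$chromosome, map$position, map$marker_id,
                    counted, other)
  miss_rate <- colMeans(is.na(dos))
  drop <- miss_rate > missing_cap
  if (any(drop)) {
    warning("dropping ", sum(drop), " marker(s) above missing-rate cap ",
            missing_cap, ": ",
            paste(utils::head(mk$marker_id[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ...")
    mk <- mk[!drop, , drop = FALSE]
    class(mk) <- c("marker_info", "data.frame")
    dos <- dos[, !drop, drop = FALSE]
  }

  list(genotypes = genotype_matrix(dos, iid, mk),
       meta = sample_meta(iid, sex, NA_character_))
}

#' Write PLINK text genotypes
#'
#' Emits a whitespace-delimited `.ped` (FID IID PAT MAT SEX PHENO + allele
#' pairs) and a 4-column `.map`. For dosage 1 the counted allele is written
#' first (`allele_a allele_b`); missing cells are written `0 0`; missing sex
#' is written as 0.
#'
#' @param G a [genotype_matrix()].
#' @param meta a [sample_meta()] covering all samples of `G` (optional; all
#'   sexes written 0 if absent).
#' @param ped_path,map_path output paths.
#' @param parents optional data.frame (`sample_id`, `father`, `mother`) for
#'   the PAT/MAT columns; defaults to 0.
#' @return invisibly, `c(ped_path, map_path)`.
#' @export
write_plink_text <- function(G, meta = NULL, ped_path, map_path,
                             parents = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$samples); L <- nrow(G$markers)
  sex_code <- rep("0", n)
  if (!is.null(meta)) {
    idx <- match(G$samples, meta$sample_id)
    if (anyNA(idx)) stop("metadata missing for sample(s): ",
                         paste(G$samples[is.na(idx)], collapse = ", "))
    sex_code <- c(male = "1", female = "2", unknown = "0")[meta$sex[idx]]
  }
  pat <- mat <- rep("0", n)
  if (!is.null(parents)) {
    idx <- match(G$samples, parents$sample_id)
    pat[!is.na(idx)] <- as.character(parents$father[idx[!is.na(idx)]])
    mat[!is.na(idx)] <- as.character(parents$mother[idx[!is.na(idx)]])
    pat[is.na(pat) | pat == ""] <- "0"
    mat[is.na(mat) | mat == ""] <- "0"
  }

  lead <- cbind(G$samples, G$samples, pat, mat, sex_code, "-9")
  if (L > 0L) {
    a <- matrix("0", n, 2L * L)
    for (j in seq_len(L)) {
      d <- G$dosages[, j]
      first <- ifelse(is.na(d), "0",
                      ifelse(d >= 1L, G$markers$allele_a[j],
                             G$markers$allele_b[j]))
      second <- ifelse(is.na(d), "0",
                       ifelse(d == 2L, G$markers$allele_a[j],
                              G$markers$allele_b[j]))
      a[, 2L * j - 1L] <- first
      a[, 2L * j] <- second
    }
    lead <- cbind(lead, a)
  }
  writeLines(apply(lead, 1L, paste, collapse = " "), ped_path)
  map <- data.frame(G$markers$chromosome, G$markers$marker_id,
                    rep(0, L), G$markers$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read / write the sample-label sidecar TSV
#'
#' Four tab-separated columns with header: `sample_id`, `sex`, `label`,
#' `population`.
#'
#' @param meta a [sample_meta()] (for writing).
#' @param path file path.
#' @return `read_sample_meta` returns a [sample_meta()].
#' @export
write_sample_meta <- function(meta, path) {
  stopifnot(inherits(meta, "sample_meta"))
  utils::write.table(as.data.frame(meta), path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  sample_meta(df$sample_id, df$sex, df$label, df$population)
}

#' Construct an answer key
#'
#' The hidden per-individual truth of a blinded benchmark: one boolean per
#' descent rule for each released individual.
#'
#' @param id blinded (or pedigree) individual identifiers.
#' @param halacha logical, matrilineal-rule labels.
#' @param law_of_return logical, grandparent-threshold-rule labels.
#' @return a `data.frame` with class `answer_key`.
#' @export
answer_key <- function(id = character(), halacha = logical(),
                       law_of_return = logical()) {
  df <- data.frame(id = as.character(id), halacha = as.logical(halacha),
                   law_of_return = as.logical(law_of_return),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate blinded ids in answer key: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  class(df) <- c("answer_key", "data.frame")
  df
}

#' Write / read an answer key as JSON
#'
#' One record per blinded individual: `{"id": ..., "halacha": ...,
#' "law_of_return": ...}`. Round-trip stable.
#'
#' @param key an [answer_key()].
#' @param path file path.
#' @return `read_answer_key` returns an [answer_key()].
#' @export
write_answer_key <- function(key, path) {
  stopifnot(inherits(key, "answer_key"))
  jsonlite::write_json(as.data.frame(key), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_answer_key
#' @export
read_answer_key <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L || NROW(df) == 0L) return(answer_key())
  answer_key(df$id, df$halacha, df$law_of_return)
}

#' Write an admixture (Q) matrix as TSV
#'
#' @param Q numeric matrix, individuals in rows, components in columns
#'   (column names = component names).
#' @param ids row identifiers.
#' @param path file path.
#' @export
write_q_matrix <- function(Q, ids, path) {
  df <- data.frame(sample_id = ids, Q, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write ancestral allele frequencies (F) as TSV
#'
#' @param F an [ancestral_frequencies()] object.
#' @param marker_ids marker identifiers (default `m1..mL`).
#' @param path file path.
#' @export
write_f_matrix <- function(F, marker_ids = NULL, path) {
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(nrow(F$F)))
  df <- data.frame(marker_id = marker_ids, F$F, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write a distance-graph edge list as TSV
#'
#' Columns `from`, `to`, `d`.
#'
#' @param graph a `distance_graph` (see [build_distance_graph()]).
#' @param path file path.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "distance_graph"))
  utils::write.table(graph$edges, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
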