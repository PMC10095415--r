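# Approach 1 core: patients x phecodes binary matrix and per-patient median
# cosine similarity within sex stratum.

#' Map diagnosis events to per-patient phecode sets
#'
#' Each patient's set is the union over their events' map lookups; a patient
#' whose codes are all unmapped keeps an empty set. Unmapped events are
#' counted and logged, never an error.
#'
#' @param events Diagnosis event data frame (pre-index filtered, see
#'   [read_diagnosis_table()]).
#' @param map A `phecode_map` from [read_phecode_map()].
#' @return Named list: patient id -> sorted character vector of phecodes.
#' @export
map_to_phecodes <- function(events, map) {
  key <- paste(events$vocabulary, events$code, sep = "\r")
  map_key <- paste(map$vocabulary, map$code, sep = "\r")
  # many-to-many: split map phecodes by key, then index
  by_key <- split(map$phecode, map_key)
  hits <- by_key[key]
  n_unmapped <- sum(vapply(hits, is.null, logical(1)))
  if (n_unmapped > 0) {
    log_msg("phecode mapping: %d event(s) had no mapped phecode", n_unmapped)
  }
  ids <- unique(events$patient_id)
  sets <- lapply(split(hits, factor(events$patient_id, levels = ids)),
                 function(x) {
                   sort(unique(as.character(unlist(x, use.names = FALSE))))
                 })
  sets[ids]
}

#' Build the sex-stratified patients x phecodes matrix
#'
#' Rows are the case patients of the requested sex (order as in `patients`);
#' columns are the union of phecodes observed in that stratum. Entries are
#' binary. Patients with no mapped phecode keep an all-zero row; they are
#' flagged here and excluded later by [median_similarity_profile()], where the
#' cosine score would be undefined.
#'
#' @param phecode_sets Named list from [map_to_phecodes()].
#' @param patients Patient data frame; control rows are ignored with a logged
#'   count (this stage models the stroke cohort only).
#' @param sex `"F"` or `"M"`.
#' @return List of class `phenotype_matrix`: `matrix` (sparse dgCMatrix,
#'   patients x phecodes), `patient_id`, `age_at_index`, `sex`,
#'   `zero_patients` (ids with empty phecode sets).
#' @export
build_phenotype_matrix <- function(phecode_sets, patients, sex) {
  sex <- match.arg(sex, SEX_LEVELS)
  n_controls <- sum(patients$label == "control")
  if (n_controls > 0) {
    log_msg("phenotype matrix: ignoring %d control row(s)", n_controls)
  }
  stratum <- patients[patients$label == "case" & patients$sex == sex, , drop = FALSE]
  if (nrow(stratum) == 0) {
    stop_strokeage("no case patients with sex %s", sex)
  }
  sets <- phecode_sets[stratum$patient_id]
  sets[vapply(sets, is.null, logical(1))] <- list(character(0))
  phecodes <- sort(unique(unlist(sets, use.names = FALSE)))
  lens <- lengths(sets)
  i <- rep(seq_len(nrow(stratum)), lens)
  j <- match(unlist(sets, use.names = FALSE), phecodes)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(stratum), max(length(phecodes), 1L)),
    dimnames = list(stratum$patient_id,
                    if (length(phecodes)) phecodes else "none")
  )
  zero <- stratum$patient_id[lens == 0]
  if (length(zero)) {
    log_msg("phenotype matrix (%s): %d patient(s) with no mapped phecode",
            sex, length(zero))
  }
  structure(
    list(matrix = m, patient_id = stratum$patient_id,
         age_at_index = stratum$age_at_index, sex = sex,
         zero_patients = zero),
    class = "phenotype_matrix"
  )
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("Phenotype matrix (%s): %d patients x %d phecodes, %d zero-profile patient(s)\n",
              x$sex, nrow(x$matrix), ncol(x$matrix), length(x$zero_patients)))
  invisible(x)
}

#' Cosine similarity of two nonnegative vectors
#'
#' For binary vectors this equals |A intersect B| / sqrt(|A| |B|).
#' Undefined (error) if either vector is all-zero; callers working on cohorts
#' exclude zero-profile patients instead.
#'
#' @param x,y Numeric nonnegative vectors of equal length.
#' @return Similarity in `[0, 1]` for nonnegative inputs.
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop_strokeage("cosine similarity is undefined for an all-zero vector")
  }
  s <- sum(x * y) / (nx * ny)
  # guard the [0, 1] bound against last-ulp rounding of the norms
  min(max(s, 0), 1)
}

#' Per-patient median cosine similarity profile
#'
#' For every patient with at least one phecode, computes the median cosine
#' similarity to every *other* retained patient in the same sex stratum (the
#' self-pair is excluded: its fixed score of 1 would bias every median
#' upward). Zero-profile patients are excluded from both roles and logged.
#'
#' The all-pairs computation runs in row blocks of `block_size` normalized
#' rows at a time; results are identical to the naive double loop for any
#' block size. The median of an even number of comparisons is the midpoint of
#' the two central values (the [stats::median()] convention).
#'
#' @param pm A `phenotype_matrix`.
#' @param block_size Rows per block; memory use is about
#'   `block_size * n * 8` bytes.
#' @return Data frame: `patient_id`, `sex`, `age_at_index`,
#'   `median_similarity`, `n_comparisons`.
#' @export
median_similarity_profile <- function(pm, block_size = 512L) {
  stopifnot(inherits(pm, "phenotype_matrix"), block_size >= 1)
  keep <- !(pm$patient_id %in% pm$zero_patients)
  if (sum(keep) < 2) {
    stop_strokeage("need >= 2 patients with nonzero phecode profiles (have %d)",
                   sum(keep))
  }
  X <- pm$matrix[keep, , drop = FALSE]
  ids <- pm$patient_id[keep]
  ages <- pm$age_at_index[keep]
  n <- nrow(X)
  # Binary rows: dot products are exact integers, so cosine is computed as
  # dot / (norm_i * norm_j) exactly as the pairwise formula does — blocked and
  # naive results agree bit-for-bit for any block size.
  norms <- sqrt(Matrix::rowSums(X^2))
  med <- numeric(n)
  for (start in seq(1L, n, by = block_size)) {
    end <- min(start + block_size - 1L, n)
    dots <- as.matrix(Matrix::tcrossprod(X[start:end, , drop = FALSE], X))
    block <- dots / (norms[start:end] %o% norms)
    # guard [0, 1] against last-ulp rounding, as cosine_similarity() does
    block[block > 1] <- 1
    block[block < 0] <- 0
    for (r in seq_len(end - start + 1L)) {
      med[start + r - 1L] <- stats::median(block[r, -(start + r - 1L)])
    }
  }
  data.frame(
    patient_id = ids,
    sex = pm$sex,
    age_at_index = ages,
    median_similarity = med,
    n_comparisons = n - 1L,
    stringsAsFactors = FALSE
  )
}
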