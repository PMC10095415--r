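# Phecode mapping, matrix construction, cosine similarity and the blocked
# median-profile computation against the naive oracle.

test_that("events map to per-patient phecode unions with set semantics", {
  map <- data.frame(
    vocabulary = c("ICD10CM", "ICD10CM"),
    code = c("I10", "E78.5"),
    phecode = c("401", "272"), stringsAsFactors = FALSE
  )
  class(map) <- c("phecode_map", "data.frame")
  ev <- data.frame(
    patient_id = c("A", "A", "A", "B"),
    vocabulary = "ICD10CM",
    code = c("I10", "E78.5", "I10", "UNMAPPED"),
    days_before_index = 1L, stringsAsFactors = FALSE
  )
  sets <- map_to_phecodes(ev, map)
  expect_equal(sets$A, c("272", "401"))   # union of lookups, duplicates once
  expect_equal(sets$B, character(0))      # unmapped -> empty set
})

test_that("phenotype matrix is binary, sex-stratified and keeps zero rows", {
  pats <- tiny_patient_df()
  pats$label <- "case"
  sets <- list(T01 = c("A"), T03 = c("A", "B"), T05 = character(0))
  pm <- build_phenotype_matrix(sets, pats, "F")
  expect_equal(dim(pm$matrix), c(4, 2))   # 4 female rows, phecodes {A,B}
  expect_equal(unname(as.matrix(pm$matrix)["T01", ]), c(1, 0))
  expect_equal(unname(as.matrix(pm$matrix)["T03", ]), c(1, 1))
  expect_true(all(as.matrix(pm$matrix) %in% 0:1))
  expect_setequal(pm$zero_patients, c("T05", "T07"))

  only_m <- pats[pats$sex == "M", ]
  expect_error(build_phenotype_matrix(sets, only_m, "F"), "sex F")
})

test_that("cosine similarity matches hand values, is symmetric and bounded", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "all-zero")

  set.seed(42)
  for (i in 1:50) {
    x <- rbinom(12, 1, 0.4); y <- rbinom(12, 1, 0.4)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_identical(cosine_similarity(x, y), cosine_similarity(y, x))
    s <- cosine_similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(cosine_similarity(x, x), 1.0)
  }
})

test_that("median profile matches per-pair enumeration on tiny strata", {
  pats <- data.frame(
    patient_id = c("a", "b", "c"), sex = "F",
    age_at_index = c(40, 50, 60), label = "case",
    stringsAsFactors = FALSE
  )
  # a = b = {P1,P2}, c = {P3,P4}: sims ab = 1, ac = bc = 0
  sets <- list(a = c("P1", "P2"), b = c("P1", "P2"), c = c("P3", "P4"))
  pm <- build_phenotype_matrix(sets, pats, "F")
  pr <- median_similarity_profile(pm)
  expect_equal(pr$median_similarity,
               c(stats::median(c(1, 0)), stats::median(c(1, 0)), 0))
  expect_equal(pr$n_comparisons, c(2L, 2L, 2L))

  # two patients: both medians equal their single pairwise similarity
  pm2 <- build_phenotype_matrix(sets[1:2], pats[1:2, ], "F")
  pr2 <- median_similarity_profile(pm2)
  expect_equal(pr2$median_similarity, c(1, 1))

  # abstract median rule on pairwise scores (1.0, 0.0, 0.5): per-patient
  # medians are the midpoints 0.5, 0.75, 0.25 — mirrored through the oracle
  X <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 1), c(0, 0, 1, 0))
  s <- c(cosine_similarity(X[1, ], X[2, ]),
         cosine_similarity(X[1, ], X[3, ]),
         cosine_similarity(X[2, ], X[3, ]))
  expect_equal(naive_median_similarity(X),
               c(stats::median(s[1:2]), stats::median(s[c(1, 3)]),
                 stats::median(s[2:3])))
})

test_that("zero-profile patients are excluded from both roles", {
  pats <- data.frame(
    patient_id = c("a", "b", "z"), sex = "M",
    age_at_index = c(40, 50, 60), label = "case", stringsAsFactors = FALSE
  )
  sets <- list(a = "P1", b = c("P1", "P2"), z = character(0))
  pm <- build_phenotype_matrix(sets, pats, "M")
  pr <- median_similarity_profile(pm)
  expect_false("z" %in% pr$patient_id)
  expect_equal(pr$n_comparisons, c(1L, 1L))
})

test_that("blocked computation equals the naive oracle for any block size", {
  set.seed(7)
  n <- 60
  X <- matrix(rbinom(n * 15, 1, 0.25), n, 15)
  X[rowSums(X) == 0, 1] <- 1L
  pats <- data.frame(patient_id = sprintf("p%03d", 1:n), sex = "F",
                     age_at_index = runif(n, 20, 90), label = "case",
                     stringsAsFactors = FALSE)
  sets <- apply(X, 1, function(r) paste0("PH", which(r == 1)))
  names(sets) <- pats$patient_id
  pm <- build_phenotype_matrix(sets, pats, "F")
  expected <- naive_median_similarity(as.matrix(pm$matrix))
  for (bs in c(1L, 7L, 64L, 512L)) {
    got <- median_similarity_profile(pm, block_size = bs)$median_similarity
    expect_identical(got, expected)
  }
})

test_that("permuting patient order permutes profiles identically", {
  set.seed(11)
  n <- 40
  X <- matrix(rbinom(n * 10, 1, 0.3), n, 10)
  X[rowSums(X) == 0, 1] <- 1L
  pats <- data.frame(patient_id = sprintf("p%02d", 1:n), sex = "F",
                     age_at_index = runif(n, 20, 90), label = "case",
                     stringsAsFactors = FALSE)
  sets <- apply(X, 1, function(r) paste0("PH", which(r == 1)))
  names(sets) <- pats$patient_id
  base <- median_similarity_profile(build_phenotype_matrix(sets, pats, "F"))
  perm <- sample(n)
  shuffled <- median_similarity_profile(
    build_phenotype_matrix(sets, pats[perm, ], "F"))
  reord <- shuffled[match(base$patient_id, shuffled$patient_id), ]
  expect_equal(reord$median_similarity, base$median_similarity)
})
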