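test_that("overlap score follows i^2/(|Pc||Kc|) with its endpoints", {
  s <- c("A", "B", "C")
  expect_equal(overlap_score(s, s), 1)
  expect_equal(overlap_score(s, c("X", "Y")), 0)
  expect_equal(overlap_score(letters[1:6], c(letters[1:5], "z")), 25 / 36)
  expect_equal(overlap_score(c("A", "B", "C", "D"), c("A", "B", "X", "Y")),
               4 / 16)
  # symmetry
  set.seed(2)
  for (rep in 1:10) {
    a <- sample(letters, sample(2:8, 1))
    b <- sample(letters, sample(2:8, 1))
    expect_equal(overlap_score(a, b), overlap_score(b, a))
  }
  expect_error(overlap_score(character(0), s), "non-empty")
})

test_that("match counting satisfies the TP/FP/FN identities", {
  known <- list(C1 = c("A", "B", "C"))
  mr <- match_complexes(list(c("A", "B", "C")), known, 0.2)
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(1L, 0L, 0L))

  mr <- match_complexes(list(c("A", "B", "C")), list(K = c("D", "E", "F")), 0.2)
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(0L, 1L, 1L))

  # OS = 4/16 = 0.25 >= 0.2 counts as a match
  mr <- match_complexes(list(c("A", "B", "C", "D")),
                        list(K = c("A", "B", "X", "Y")), 0.2)
  expect_equal(mr$tp, 1L)

  expect_error(match_complexes(list(c("A")), list(), 0.2), "empty")

  set.seed(8)
  ids <- sprintf("P%02d", 1:30)
  for (rep in 1:10) {
    pred <- replicate(sample(1:6, 1), sample(ids, sample(2:6, 1)),
                      simplify = FALSE)
    kn <- replicate(sample(1:6, 1), sample(ids, sample(2:6, 1)),
                    simplify = FALSE)
    names(kn) <- sprintf("K%d", seq_along(kn))
    mr <- match_complexes(pred, kn, 0.2)
    expect_equal(mr$tp + mr$fp, length(pred))
    expect_equal(mr$matched_known + mr$fn, length(kn))
  }
})

test_that("sensitivity, specificity and f-measure reproduce exact rational values", {
  expect_equal(sensitivity(1, 1), 0.5)
  expect_equal(sensitivity(0, 5), 0)
  expect_equal(sensitivity(44, 162), 44 / 206, tolerance = 1e-12)
  expect_equal(round(sensitivity(44, 162), 9), 0.213592233)

  expect_equal(specificity(44, 134), 44 / 178, tolerance = 1e-12)
  expect_equal(round(specificity(44, 134), 9), 0.247191011)
  expect_equal(round(specificity(13, 5), 9), 0.722222222)
  expect_equal(specificity(0, 1), 0)

  expect_equal(round(f_measure(0.872787611, 0.391952310), 9), 0.540966747)
  expect_equal(round(f_measure(0.213592233, 0.247191011), 9), 0.229166667)
  expect_equal(f_measure(0.3, 0.3), 0.3)  # harmonic-mean idempotence

  expect_error(sensitivity(0, 0), "positive")
  expect_error(specificity(0, 0), "positive")
  expect_error(f_measure(0, 0), "positive")
})

test_that("f-measure identity 2a/(x+y) holds for match-derived rates", {
  # with a matched count a over known-denominator x and predicted-denominator
  # y: f(a/x, a/y) = 2a/(x+y) exactly
  cases <- list(c(44, 206, 178), c(32, 206, 61), c(7, 30, 12))
  for (cs in cases) {
    a <- cs[1]; x <- cs[2]; y <- cs[3]
    expect_equal(f_measure(a / x, a / y), 2 * a / (x + y), tolerance = 1e-14)
  }
  expect_equal(2 * 44 / (206 + 178), 88 / 384)
  expect_equal(round(88 / 384, 9), 0.229166667)
  expect_equal(round(2 * 32 / (206 + 61), 9), 0.239700375)
  # min-max sandwich
  set.seed(4)
  for (rep in 1:20) {
    sn <- runif(1); sp <- runif(1)
    f <- f_measure(sn, sp)
    expect_gte(f, min(sn, sp) - 1e-12)
    expect_lte(f, max(sn, sp) + 1e-12)
  }
})

test_that("overlapping rate averages per-protein cluster membership", {
  r <- overlapping_rate(list(c("A", "B", "C"), c("D", "E", "F")))
  expect_equal(r$rate, 1)
  expect_equal(r$frac_multi, 0)

  r <- overlapping_rate(list(c("A", "B", "C"), c("A", "D", "E")))
  expect_equal(r$rate, 6 / 5)
  expect_equal(r$frac_multi, 1 / 5)

  r <- overlapping_rate(list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(r$rate, 2)
  expect_equal(r$frac_multi, 1)

  expect_error(overlapping_rate(list()), "no clusters")
})

test_that("hypergeometric tail equals the brute-force combinatorial sum", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / 252)
  expect_equal(hypergeom_pvalue(30, 6, 9, 0), 1)
  expect_equal(hypergeom_pvalue(20, 6, 8, 4),
               oracle_hyper_tail(20, 6, 8, 4), tolerance = 1e-12)

  set.seed(12)
  for (rep in 1:50) {
    N <- sample(5:25, 1)
    C <- sample(1:N, 1)
    F_ <- sample(1:N, 1)
    k <- sample(0:min(C, F_), 1)
    expect_equal(hypergeom_pvalue(N, C, F_, k),
                 oracle_hyper_tail(N, C, F_, k), tolerance = 1e-12)
  }

  # monotone non-increasing in k
  for (k in 1:5) {
    expect_lte(hypergeom_pvalue(30, 8, 10, k),
               hypergeom_pvalue(30, 8, 10, k - 1) + 1e-15)
  }
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "k_hit")
})

test_that("main-function assignment minimises the enrichment P-value", {
  ann <- list(
    A = "10.01", B = "10.01", C = "10.01", D = "10.01", E = "10.01",
    X = "20.02", Y = "20.02", Z = c("10.01", "20.02"))
  res <- assign_main_function(c("A", "B", "C", "D", "E"), ann, 20)
  expect_equal(res$best_category, "10.01")
  expect_equal(res$k_in, 5L)
  expect_equal(res$p_value, hypergeom_pvalue(20, 5, 6, 5))

  res <- assign_main_function(c("Q1", "Q2"), ann, 20)
  expect_true(is.na(res$best_category))

  # identical hit patterns tie; the lexicographically smaller code wins
  ann2 <- list(A = c("14.07", "10.03"), B = c("14.07", "10.03"),
               C = c("14.07", "10.03"))
  res <- assign_main_function(c("A", "B", "C"), ann2, 10)
  expect_equal(res$best_category, "10.03")
})

test_that("complex-complex overlap pairs list exactly the sharing clusters", {
  pairs <- complex_overlap_network(list(c("A", "B", "C"), c("C", "D", "E"),
                                        c("F", "G", "H")))
  expect_equal(unname(pairs), matrix(c(1L, 2L), 1))

  expect_equal(nrow(complex_overlap_network(
    list(c("A", "B"), c("C", "D")))), 0L)

  pairs <- complex_overlap_network(list(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(nrow(pairs), 3L)
})

test_that("catalog and annotation files load with filtering rules applied", {
  f <- withr::local_tempfile()
  writeLines(c("C1\tA\tB\tC", "Singleton\tX", "C2\tD\tE", "# note"), f)
  cat_ <- load_complex_catalog(f)
  expect_equal(names(cat_), c("C1", "C2"))
  expect_equal(cat_$C1, c("A", "B", "C"))

  writeLines(c("A\t10.01", "A\t20.02", "B\t10.01"), f)
  ann <- load_annotations(f)
  expect_equal(ann$A, c("10.01", "20.02"))
  expect_equal(ann$B, "10.01")
})

test_that("the full evaluation report is internally consistent", {
  pred <- list(c("A", "B", "C"), c("C", "D", "E"), c("X", "Y", "Z"))
  known <- list(K1 = c("A", "B", "C"), K2 = c("D", "E", "F", "G"))
  ann <- list(A = "1.1", B = "1.1", C = "1.1", D = "2.2", E = "2.2")
  rep <- evaluate_clusters(pred, known, 0.2, annotations = ann, n_total = 10)
  expect_equal(rep$match$tp + rep$match$fp, length(pred))
  expect_equal(rep$match$matched_known + rep$match$fn, length(known))
  expect_equal(rep$sensitivity, rep$match$matched_known / length(known))
  expect_equal(rep$specificity, rep$match$tp / length(pred))
  expect_equal(length(rep$enrichment), length(pred))
  expect_true(is.na(rep$enrichment[[3]]$best_category))
  out <- capture.output(print(rep))
  expect_true(any(grepl("^f_measure\t", out)))
})
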