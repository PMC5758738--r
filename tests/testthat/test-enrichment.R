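test_that("GMT files parse, deduplicate and round-trip", {
  f <- withr::local_tempfile(lines = c(
    "T1\tfirst term\tA\tB\tC",
    "T2\tsecond term\tb\tB\tD"))
  ann <- read_gmt(f)
  expect_identical(ann$terms$T1, c("A", "B", "C"))
  expect_identical(ann$terms$T2, c("B", "D"))     # case-folded, deduplicated
  expect_setequal(ann$universe, c("A", "B", "C", "D"))

  bad <- withr::local_tempfile(lines = c("T1\tdesc\tA", "T2\tonly-desc"))
  expect_error(read_gmt(bad), "line 2")

  set.seed(19)
  terms <- lapply(1:50, function(i) sample(LETTERS, sample(3:10, 1)))
  names(terms) <- sprintf("T%02d", 1:50)
  ann2 <- annotation_set(terms)
  f2 <- withr::local_tempfile()
  write_gmt(ann2, f2)
  back <- read_gmt(f2)
  expect_identical(back$terms, ann2$terms)
  expect_identical(back$universe, ann2$universe)
})

test_that("the hypergeometric upper tail matches combinatorial enumeration", {
  expect_equal(hypergeom_p(0, 4, 5, 10), 1)
  expect_equal(hypergeom_p(4, 4, 5, 10), 6 / 252)   # C(4,4) C(6,1) / C(10,5)
  expect_error(hypergeom_p(5, 4, 5, 10))

  set.seed(47)
  for (i in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_p(k, K, n, N), oracle_hyper_tail(k, K, n, N),
                 tolerance = 1e-12)
  }
  # non-increasing in k at fixed margins
  ps <- vapply(0:5, hypergeom_p, numeric(1), K = 8, n = 10, N = 40)
  expect_true(all(diff(ps) <= 0))
})

test_that("over-representation handles degenerate and single-term cases", {
  ann <- annotation_set(list(T1 = LETTERS[1:5]), universe = LETTERS)
  res <- ora(LETTERS[1:5], ann)
  expect_equal(res$p, 1 / choose(26, 5), tolerance = 1e-12)
  expect_equal(res$q, res$p)   # single tested term: q = p
  expect_true(res$significant)

  ann2 <- annotation_set(list(T1 = c("A", "B"), T2 = c("C", "D")),
                         universe = LETTERS)
  res2 <- ora(c("X", "Y", "Z"), ann2)
  expect_true(all(res2$k == 0))
  expect_true(all(res2$p == 1))
  expect_error(ora(character(0), ann2))
  expect_message(ora(c("A", "NOT-IN-UNIVERSE-1"), ann2), "dropped 1")

  # q is monotone in p-rank and bounded by 1
  set.seed(53)
  terms <- lapply(1:30, function(i) sample(LETTERS, 6))
  names(terms) <- sprintf("T%02d", 1:30)
  res3 <- ora(sample(LETTERS, 8), annotation_set(terms, universe = LETTERS))
  expect_true(all(diff(res3$q) >= -1e-12))
  expect_true(all(res3$q >= res3$p))
  expect_true(all(res3$q <= 1))
})

test_that("planted enriched terms are exactly the significant calls", {
  spec <- synthetic_spec(rng_seed = 31L)
  universe <- sprintf("U%03d", 1:382)
  query <- sprintf("U%03d", 1:45)
  ann <- make_annotations(spec, query = query, universe = universe)
  res <- ora(query, ann$annotation)
  expect_setequal(res$term_id[res$significant], ann$truth$enriched_terms)
  expect_length(ann$truth$enriched_terms, 43L)
})

test_that("kappa grouping collapses identical terms and separates disjoint ones", {
  ann <- annotation_set(list(T1 = c("A", "B", "C"), T2 = c("A", "B", "C"),
                             T3 = c("X", "Y", "Z")),
                        universe = c(LETTERS, "AA"))
  res <- ora(c("A", "B", "C", "X", "Y", "Z"), ann, alpha = 0.05)
  grp <- kappa_grouping(res, ann)
  expect_true(all(res$significant))
  ids <- stats::setNames(grp$kappa_group, grp$term_id)
  expect_equal(ids[["T1"]], ids[["T2"]])
  expect_false(ids[["T3"]] == ids[["T1"]])
  expect_equal(attr(grp, "n_groups"), 2L)
  # group labels point at the most significant member
  expect_true(all(grp$group[!is.na(grp$group)] %in% grp$term_id))
})

test_that("grouping is invariant to term input order", {
  spec <- synthetic_spec(rng_seed = 61L)
  universe <- sprintf("U%03d", 1:382)
  query <- sprintf("U%03d", 1:45)
  ann <- make_annotations(spec, query = query, universe = universe)$annotation
  res <- kappa_grouping(ora(query, ann), ann)
  ann_rev <- annotation_set(rev(ann$terms), ann$term_names,
                            universe = ann$universe)
  res_rev <- kappa_grouping(ora(query, ann_rev), ann_rev)
  m1 <- stats::setNames(res$group, res$term_id)
  m2 <- stats::setNames(res_rev$group, res_rev$term_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m1))])
  expect_equal(attr(res, "n_groups"), 9L)
})

test_that("nine planted term blocks produce nine kappa groups", {
  spec <- synthetic_spec(rng_seed = 42L)
  universe <- sprintf("U%03d", 1:382)
  query <- sprintf("U%03d", 1:45)
  ann <- make_annotations(spec, query = query, universe = universe)
  res <- kappa_grouping(ora(query, ann$annotation), ann$annotation)
  expect_equal(attr(res, "n_groups"), 9L)
  # groups partition the significant terms
  sig <- res[res$significant, ]
  expect_false(anyNA(sig$kappa_group))
  expect_true(all(is.na(res$kappa_group[!res$significant])))
  # block structure is respected: same planted block implies same group
  for (b in seq_along(ann$truth$blocks)) {
    gids <- sig$kappa_group[sig$term_id %in% ann$truth$blocks[[b]]]
    expect_length(unique(gids), 1L)
  }
})
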