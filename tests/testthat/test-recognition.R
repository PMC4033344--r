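make_gallery <- function(mats, ids) {
  gait_gallery(lapply(mats, function(m) structure(m, class = "gait_features")),
               subject_ids = ids)
}

test_that("nearest-neighbour identification returns the closest subject", {
  set.seed(201)
  mats <- lapply(1:4, function(i) matrix(rnorm(6), 3, 2))
  gal <- make_gallery(mats, c("a", "b", "c", "d"))
  res <- identify_probe(mats[[3]], gal)
  expect_equal(res$subject_id, "c")
  expect_equal(res$ranking$distance[1], 0)

  # equidistant entries: first-inserted wins
  tie <- make_gallery(list(matrix(1, 2, 2), matrix(1, 2, 2)), c("x", "y"))
  expect_equal(identify_probe(matrix(0, 2, 2), tie)$subject_id, "x")

  expect_error(identify_probe(mats[[1]],
                              structure(list(features = list(),
                                             subject_ids = character(0)),
                                        class = "gait_gallery")),
               "empty")
})

test_that("identification agrees with an exhaustive distance-matrix oracle", {
  set.seed(202)
  pop <- fixture_population(8, 2, 24)
  sp <- split_gallery_probe(pop)
  g_tmpl <- lapply(sp$gallery, build_agdi)
  p_tmpl <- lapply(sp$probe, build_agdi)
  basis <- fit_basis(g_tmpl, d = 10)
  gal <- gait_gallery(lapply(g_tmpl, project_template, basis = basis))
  hits <- 0
  for (j in seq_along(p_tmpl)) {
    pf <- project_template(p_tmpl[[j]], basis)
    res <- identify_probe(pf, gal)
    # oracle: brute-force all pairwise distances
    d <- vapply(gal$features, function(g) oracle_distance(unclass(g),
                                                          unclass(pf)),
                numeric(1))
    expect_equal(res$subject_id, gal$subject_ids[which.min(d)])
    hits <- hits + (res$subject_id == p_tmpl[[j]]$subject_id)
  }
  expect_equal(hits / length(p_tmpl),
               mean(vapply(seq_along(p_tmpl), function(j) {
                 pf <- project_template(p_tmpl[[j]], basis)
                 d <- vapply(gal$features, feature_distance, numeric(1), b = pf)
                 gal$subject_ids[which.min(d)] == p_tmpl[[j]]$subject_id
               }, logical(1))))
})

test_that("similarity is the negative distance and reverses orderings", {
  set.seed(203)
  A <- matrix(rnorm(8), 4, 2)
  expect_equal(similarity(A, A), 0)
  for (i in 1:5) {
    X <- matrix(rnorm(8), 4, 2); Y <- matrix(rnorm(8), 4, 2)
    Z <- matrix(rnorm(8), 4, 2)
    expect_equal(similarity(X, Y), -feature_distance(X, Y))
    expect_equal(feature_distance(X, Y) < feature_distance(X, Z),
                 similarity(X, Y) > similarity(X, Z))
  }
})

test_that("z-normed similarities have mean 0, sample s.d. 1 per probe", {
  set.seed(204)
  mats <- lapply(1:6, function(i) matrix(rnorm(6), 3, 2))
  gal <- make_gallery(mats, letters[1:6])
  probe <- matrix(rnorm(6), 3, 2)
  zn <- znorm_similarities(probe, gal)
  expect_equal(mean(zn$z_similarity), 0, tolerance = 1e-12)
  expect_equal(sd(zn$z_similarity), 1, tolerance = 1e-12)

  # two-entry gallery: closed-form +/- 1/sqrt(2)
  gal2 <- make_gallery(mats[1:2], c("a", "b"))
  zn2 <- znorm_similarities(probe, gal2)
  expect_equal(sort(zn2$z_similarity), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # degenerate: all similarities equal
  same <- make_gallery(list(mats[[1]], mats[[1]]), c("a", "b"))
  expect_error(znorm_similarities(probe, same), "degenerate")
})

test_that("z-norming never changes the top-ranked identity", {
  set.seed(205)
  mats <- lapply(1:8, function(i) matrix(rnorm(10), 5, 2))
  gal <- make_gallery(mats, letters[1:8])
  for (i in 1:10) {
    probe <- matrix(rnorm(10), 5, 2)
    top_id <- identify_probe(probe, gal)$subject_id
    zn <- znorm_similarities(probe, gal)
    expect_equal(zn$subject_id[which.max(zn$z_similarity)], top_id)
  }
})

test_that("EER is 0 for separated scores and 0.5 for identical ones", {
  r <- roc_and_eer(genuine = c(5, 6, 7), impostor = c(1, 2, 3))
  expect_equal(r$eer, 0)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(roc_and_eer(x, x)$eer, 0.5)
  expect_error(roc_and_eer(numeric(0), 1), "empty")
  expect_error(roc_and_eer(1, numeric(0)), "empty")
})

test_that("FAR falls and FRR rises as the threshold tightens", {
  set.seed(206)
  r <- roc_and_eer(rnorm(500, 1), rnorm(500, -1))
  expect_true(all(diff(r$roc$far) <= 0))
  expect_true(all(diff(r$roc$frr) >= 0))
  expect_gte(r$eer, 0); expect_lte(r$eer, 0.5)
})

test_that("EER is invariant under strictly increasing score transforms", {
  set.seed(207)
  g <- rnorm(400, 0.8); i <- rnorm(400, -0.8)
  e1 <- roc_and_eer(g, i)$eer
  f <- function(x) exp(x / 2) + x          # strictly increasing
  e2 <- roc_and_eer(f(g), f(i))$eer
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("self-matching probes give perfect identification and verification", {
  pop <- fixture_population(5, 1, 20, seed = 77)
  rep <- evaluate_recognition(pop, pop, kind = "agdi", d = 10)
  expect_equal(rep$rank1, 1)
  expect_equal(rep$eer, 0)
  expect_true(all(diff(rep$cmc$rate) >= 0))
  expect_equal(rep$cmc$rate[nrow(rep$cmc)], 1)
})

test_that("pipeline evaluation matches an oracle recomputation", {
  pop <- fixture_population(6, 2, 24, seed = 88)
  sp <- split_gallery_probe(pop)
  rep <- evaluate_recognition(sp$gallery, sp$probe, kind = "agdi", d = 12)
  # recompute rank-1 from scratch with explicit stages
  g_tmpl <- lapply(sp$gallery, build_agdi)
  p_tmpl <- lapply(sp$probe, build_agdi)
  basis <- fit_basis(g_tmpl, d = 12)
  gf <- lapply(g_tmpl, project_template, basis = basis)
  ids <- vapply(g_tmpl, `[[`, character(1), "subject_id")
  hit <- vapply(p_tmpl, function(pt) {
    d <- vapply(gf, function(g) oracle_distance(unclass(g),
                                                unclass(project_template(pt, basis))),
                numeric(1))
    ids[which.min(d)] == pt$subject_id
  }, logical(1))
  expect_equal(rep$rank1, mean(hit))
  expect_true(all(diff(rep$cmc$rate) >= 0))
})

test_that("probes of unenrolled subjects count as forced errors", {
  pop <- fixture_population(4, 2, 20, seed = 99)
  sp <- split_gallery_probe(pop)
  gal <- sp$gallery[1:3]                  # S04 not enrolled
  rep <- evaluate_recognition(gal, sp$probe, kind = "agdi", d = 8)
  expect_true(is.na(rep$decisions$rank[rep$decisions$probe_subject == "S04"]))
  expect_lte(rep$cmc$rate[nrow(rep$cmc)], 3 / 4)
})

test_that("leave-one-out protocol runs and stays consistent", {
  pop <- fixture_population(5, 2, 20, seed = 111)
  sp <- split_gallery_probe(pop)
  rep <- evaluate_recognition(sp$gallery, sp$probe, kind = "agdi", d = 8,
                              protocol = "leave-one-out")
  expect_true(all(diff(rep$cmc$rate) >= 0))
  expect_gte(rep$rank1, 0.6)              # easy synthetic population
})
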