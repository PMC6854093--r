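# Goodness of fit, model selection and multi-network comparison.

make_er_spec <- function(n, p, label = "er") {
  model_spec("er_growth", n = n, p = p, seed = seed_spec("complete", k = 5), label = label)
}

test_that("goodness of fit ranks a matching model ahead of a mismatched one", {
  set.seed(41)
  g_obs <- generate_network(make_er_spec(80, 0.08))
  sch <- subsample_scheme(0.3, 40, 40, seed = 17)
  rep <- assess_gof(g_obs,
                    list(make_er_spec(80, 0.08, "matched"), make_er_spec(80, 0.5, "dense")),
                    stats = c("triangles", "deg_q50"), scheme = sch)
  expect_s3_class(rep, "netboot_gof")
  expect_equal(dim(rep$distances$ks), c(2, 2))
  # the dense model's subsamples live on a disjoint range: KS = 1, ranked last
  expect_equal(unname(rep$distances$ks["dense", "deg_q50"]), 1)
  expect_true(all(rep$distances$ks["matched", ] <= rep$distances$ks["dense", ]))
  expect_equal(rep$orderings$ks$triangles[1], "matched")
})

test_that("gof orderings are invariant to candidate listing order", {
  set.seed(42)
  g_obs <- generate_network(make_er_spec(60, 0.1))
  sch <- subsample_scheme(0.3, 30, 30, seed = 19)
  c1 <- make_er_spec(60, 0.1, "a"); c2 <- make_er_spec(60, 0.4, "b")
  r12 <- assess_gof(g_obs, list(c1, c2), stats = "triangles", scheme = sch)
  r21 <- assess_gof(g_obs, list(c2, c1), stats = "triangles", scheme = sch)
  expect_equal(r12$orderings$ks$triangles, r21$orderings$ks$triangles)
})

test_that("gof warns when candidate size mismatches the observed network", {
  set.seed(43)
  g_obs <- generate_network(make_er_spec(40, 0.1))
  sch <- subsample_scheme(0.3, 10, 10, seed = 23)
  expect_warning(assess_gof(g_obs, list(make_er_spec(30, 0.1)), stats = "triangles", scheme = sch),
                 "observed network")
})

test_that("selectors reach perfect training separation on separable candidates", {
  sch <- subsample_scheme(0.5, 20, 60, seed = 29)
  cands <- list(make_er_spec(40, 0.02, "sparse"), make_er_spec(40, 0.6, "dense"))
  sel <- fit_selector(cands, stats = c("triangles", "deg_q50"), scheme = sch,
                      learner = learner_spec("rf", ntree = 200))
  expect_s3_class(sel, "netboot_selector")
  # probe rows drawn fresh from each model are classified to their source
  probe1 <- resample_model(cands[[1]], c("triangles", "deg_q50"),
                           subsample_scheme(0.5, 5, 30, seed = 31), "independent")
  probe2 <- resample_model(cands[[2]], c("triangles", "deg_q50"),
                           subsample_scheme(0.5, 5, 30, seed = 37), "independent")
  s1 <- predict(sel, probe1$values)
  s2 <- predict(sel, probe2$values)
  expect_true(mean(apply(s1, 1, which.max) == 1) == 1)
  expect_true(mean(apply(s2, 1, which.max) == 2) == 1)
  expect_equal(dim(s1), c(30, 2))
})

test_that("selector predictions are deterministic given the scheme seed", {
  sch <- subsample_scheme(0.5, 10, 30, seed = 41)
  cands <- list(make_er_spec(30, 0.05), make_er_spec(30, 0.5))
  sel1 <- fit_selector(cands, stats = c("triangles", "deg_q50"), scheme = sch,
                       learner = learner_spec("knn"))
  sel2 <- fit_selector(cands, stats = c("triangles", "deg_q50"), scheme = sch,
                       learner = learner_spec("knn"))
  probe <- matrix(c(3, 2, 100, 12), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("triangles", "deg_q50")))
  expect_identical(predict(sel1, probe), predict(sel2, probe))
})

test_that("model selection reports majority, proportions and confidence", {
  sch <- subsample_scheme(0.5, 40, 60, seed = 43)
  cands <- list(make_er_spec(40, 0.05, "sparse"), make_er_spec(40, 0.6, "dense"))
  sel <- fit_selector(cands, stats = c("triangles", "deg_q50"), scheme = sch,
                      learner = learner_spec("rf", ntree = 200))
  set.seed(44)
  g_obs <- generate_network(cands[[2]])
  res <- select_model(sel, g_obs)
  expect_s3_class(res, "netboot_selection")
  expect_equal(res$selected_label, "dense")
  expect_equal(sum(res$proportions), 1)
  expect_equal(res$confidence, max(res$proportions))
  expect_equal(length(res$assignments), 40)
  expect_false(res$tie)
  # reproducible under the same scheme seed
  res2 <- select_model(sel, g_obs)
  expect_identical(res$proportions, res2$proportions)
})

test_that("selection enforces equal fractions and breaks ties deterministically", {
  sch <- subsample_scheme(0.5, 10, 30, seed = 47)
  cands <- list(make_er_spec(30, 0.05), make_er_spec(30, 0.5))
  sel <- fit_selector(cands, stats = c("triangles", "deg_q50"), scheme = sch,
                      learner = learner_spec("knn"))
  set.seed(48)
  g_obs <- generate_network(cands[[1]])
  expect_error(select_model(sel, g_obs, scheme = subsample_scheme(0.4, 10, 30, seed = 47)),
               "fraction")
  # synthetic tie: equal proportions flag the tie and pick the lowest index
  props <- c(a = 0.5, b = 0.5)
  winners <- which(props == max(props))
  expect_equal(unname(winners[1L]), 1L)
  expect_length(winners, 2L)
})

test_that("multi-network comparison is symmetric with near-zero self-similarity", {
  set.seed(51)
  g1 <- generate_network(make_er_spec(60, 0.1))
  g2 <- generate_network(make_er_spec(60, 0.5))
  sch <- subsample_scheme(0.3, 40, 40, seed = 53)
  cmpr <- compare_networks(list(a = g1, a_dup = g1, b = g2),
                           stats = c("triangles", "deg_q50"), scheme = sch)
  expect_equal(dim(cmpr$per_stat), c(3, 3, 2))
  expect_equal(cmpr$aggregate, t(cmpr$aggregate)) # KS symmetry
  expect_true(all(diag(cmpr$aggregate) == 0))
  # duplicate graph: only subsample noise separates the pair
  expect_lt(cmpr$aggregate["a", "a_dup"], cmpr$aggregate["a", "b"])
  expect_error(compare_networks(list(g1)), "2")
})

test_that("gof and selection results serialize with provenance", {
  set.seed(55)
  g_obs <- generate_network(make_er_spec(40, 0.1))
  sch <- subsample_scheme(0.3, 10, 10, seed = 59)
  rep <- assess_gof(g_obs, list(make_er_spec(40, 0.1)), stats = "triangles", scheme = sch)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_gof_json(rep, jp); write_gof_tsv(rep, tp)
  parsed <- jsonlite::read_json(jp)
  expect_equal(parsed$scheme$seed, 59)
  expect_equal(parsed$candidates[[1]]$family, "er_growth")
  expect_true(file.exists(tp))
  sel <- fit_selector(list(make_er_spec(40, 0.05), make_er_spec(40, 0.5)),
                      stats = c("triangles", "deg_q50"), scheme = sch,
                      learner = learner_spec("knn"))
  res <- select_model(sel, g_obs)
  sp <- tempfile(fileext = ".json")
  write_selection_json(res, sp)
  parsed <- jsonlite::read_json(sp)
  expect_equal(parsed$B_used, 10)
  expect_true(parsed$selected %in% 1:2)
})
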