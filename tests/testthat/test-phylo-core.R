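# Tree/trait core: Newick I/O, validation, polytomy resolution, dataset
# construction and covariate standardization.

test_that("Newick parsing validates structure and round-trips lengths", {
  tr <- suppressMessages(read_newick("((A:1,B:1):1,C:2);"))
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1, 2]
  expect_length(root_children, 2)

  expect_error(suppressMessages(read_newick("((A:1,A:1):1,C:2);")),
               "duplicate tip")
  expect_error(suppressMessages(read_newick("((A:1,B:1:1,C:2);")),
               "malformed")

  tmp <- tempfile(fileext = ".nwk")
  tr0 <- random_tree(15, seed = 4)
  write_newick(tr0, tmp)
  tr1 <- suppressMessages(read_newick(tmp))
  expect_equal(sort(tr1$tip.label), sort(tr0$tip.label))
  m0 <- ape::cophenetic.phylo(tr0)
  m1 <- ape::cophenetic.phylo(tr1)[rownames(m0), colnames(m0)]
  expect_lt(max(abs(m0 - m1)), 1e-9)
})

test_that("tree validation rejects negative lengths and too-few tips", {
  tr <- toy_tree4()
  tr$edge.length[2] <- -0.1
  expect_error(validate_tree(tr), "non-negative")
  expect_error(suppressMessages(read_newick("(A:1);")), "2 tips")
})

test_that("polytomy resolution is deterministic and invisible to analyses", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,(D:1,E:1):1);")
  r1 <- resolve_polytomies(poly)
  r2 <- resolve_polytomies(poly)
  expect_true(ape::is.binary.phylo(r1))
  expect_identical(ape::write.tree(r1), ape::write.tree(r2))

  y <- c(A = 1, B = 1, C = 0, D = 0, E = 1)
  expect_equal(mk_loglik(poly, y, 0.3, 0.5),
               mk_loglik(r1, y, 0.3, 0.5), tolerance = 1e-12)
})

test_that("analysis dataset applies sex priority and any-black scoring", {
  tab <- toy_trait_table()
  tr <- toy_tree4()
  ds <- suppressMessages(build_analysis_dataset(tab, "head", "male", tr,
                                                covariates = character(0)))
  yy <- setNames(ds$y, ds$species)
  # male black beats female non-black under male priority
  expect_equal(yy[["A"]], 1L)
  # only a female record exists: fallback uses it
  expect_equal(yy[["B"]], 0L)
  # both sexes scored: the priority sex decides
  expect_equal(yy[["D"]], 0L)
  ds_f <- suppressMessages(build_analysis_dataset(tab, "head", "female", tr,
                                                  covariates = character(0)))
  expect_equal(setNames(ds_f$y, ds_f$species)[["A"]], 0L)
  expect_equal(setNames(ds_f$y, ds_f$species)[["D"]], 1L)
})

test_that("a species with any black specimen among several is black", {
  tr <- toy_tree4()
  tab <- data.frame(
    species = rep("A", 5), sex = "M", region = "head",
    skin = c("non-black", "non-black", "black", "non-black", "non-black"),
    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(species = c("B", "C", "D"), sex = "M",
                               region = "head", skin = "non-black"))
  ds <- suppressMessages(build_analysis_dataset(tab, "head", "male", tr))
  expect_equal(ds$y[ds$species == "A"], 1L)
})

test_that("covariates are standardized with log transforms for mass and UV", {
  tab <- toy_trait_table()
  ds <- suppressMessages(build_analysis_dataset(tab, "head", "male",
                                                toy_tree4()))
  for (v in c("mass_g", "uv_b")) {
    expect_lt(abs(mean(ds[[v]])), 1e-8)
    expect_lt(abs(sd(ds[[v]]) - 1), 1e-8)
  }
  # one-hot feather colours against the brown reference
  expect_true(all(c("feather_white", "feather_black") %in% names(ds)))
  expect_false("feather_brown" %in% names(ds))
})

test_that("species mismatches are reported, not dropped silently", {
  tab <- toy_trait_table()
  tab$species[tab$species == "D"] <- "D_new_name"
  ds <- suppressMessages(build_analysis_dataset(
    tab, "head", "male", toy_tree4(),
    alias = c(D_new_name = "D"), covariates = character(0)))
  rec <- attr(ds, "reconciliation")
  expect_equal(rec$n_aliased, 2L)
  expect_equal(sort(ds$species), c("A", "B", "C", "D"))

  other <- ape::read.tree(text = "(X:1,Y:1);")
  expect_error(suppressMessages(
    build_analysis_dataset(toy_trait_table(), "head", "male", other)),
    "match the tree")
})

test_that("trait tables reject non-binary skin codings and round-trip", {
  tab <- toy_trait_table()
  tab$skin[1] <- "yellow"
  expect_error(validate_trait_table(tab), "binary")
  tmp <- tempfile(fileext = ".csv")
  write_trait_table(toy_trait_table(), tmp)
  back <- read_trait_table(tmp)
  expect_equal(back$species, toy_trait_table()$species)
  expect_equal(back$mass_g, toy_trait_table()$mass_g)
})

test_that("standardization meets the tolerance invariants on random data", {
  set.seed(8)
  for (i in 1:5) {
    x <- standardize(rnorm(50, mean = runif(1, -5, 5), sd = runif(1, .1, 9)))
    expect_lt(abs(mean(x)), 1e-8)
    expect_lt(abs(sd(x) - 1), 1e-8)
  }
  expect_error(standardize(rep(2, 10)), "constant")
})
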