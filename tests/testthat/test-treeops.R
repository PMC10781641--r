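test_that("newick round trip preserves topology, labels and ages", {
  sim <- simulate_bd_tree(sim_config(12, 0.35, 0.1, seed = 8, max_tips = 500))
  tf <- tempfile(fileext = ".nwk")
  write_newick(sim$tree, tf)
  back <- read_newick(tf)
  expect_identical(sort(back$tip.label), sort(sim$tree$tip.label))
  a0 <- node_ages(sim$tree)
  a1 <- node_ages(back)
  expect_equal(sort(a1), sort(a0), tolerance = 1e-9)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(sim$tree))), 0)
})

test_that("ages come from path arithmetic with extant calibration", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_newick(tf)
  ages <- node_ages(tr)
  expect_equal(unname(ages[match("A", tr$tip.label)]), 0)
  expect_equal(max(ages), 2)  # root age
})

test_that("invalid newick inputs are refused", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1);", tf)           # basal trichotomy
  expect_error(read_newick(tf), "unsupported topology")
  writeLines("((A:1,B:1,C:1):1,D:2);", tf)   # rooted but with a polytomy
  expect_error(read_newick(tf), "unsupported topology")
  writeLines("((A,B),C);", tf)
  expect_error(read_newick(tf), "branch length")
})

test_that("habitat tables round-trip and validate states", {
  hab <- c(t1 = "marine", t2 = "freshwater", t3 = "terrestrial")
  tf <- tempfile(fileext = ".tsv")
  write_habitat(hab, tf)
  expect_identical(read_habitat(tf), hab)
  expect_error(write_habitat(c(t1 = "lacustrine"), tf), "unknown habitat")
})

test_that("partition extraction induces the right subtrees", {
  tr <- ape::read.tree(text = "((m1:1,f1:1):1,t1:2);")
  hab <- c(m1 = "marine", f1 = "freshwater", t1 = "terrestrial")
  nm <- extract_partition(tr, hab, "non-marine")
  expect_setequal(nm$tip.label, c("f1", "t1"))

  all_marine <- c(m1 = "marine", f1 = "marine", t1 = "marine")
  same <- extract_partition(tr, all_marine, "marine")
  expect_identical(same$edge, tr$edge)

  expect_error(extract_partition(tr, hab, "marine"), "at least 2")
  expect_error(extract_partition(tr, hab[-1], "non-marine"), "without a habitat")
})

test_that("partition subtrees keep absolute node ages, even fully extinct ones", {
  sim <- simulate_bd_tree(sim_config(20, 0.3, 0.15, seed = 17,
                                     habitat_transition_rate = 0.3,
                                     max_tips = 2000))
  full_ages <- node_ages(sim$tree)
  names(full_ages)[seq_len(ape::Ntip(sim$tree))] <- sim$tree$tip.label
  for (p in c("marine", "non-marine", "freshwater", "terrestrial")) {
    sub <- tryCatch(extract_partition(sim$tree, sim$habitat, p),
                    error = function(e) NULL)
    if (is.null(sub)) next
    sub_ages <- node_ages(sub)
    idx <- match(sub$tip.label, sim$tree$tip.label)
    expect_equal(unname(sub_ages[seq_len(ape::Ntip(sub))]),
                 unname(full_ages[idx]), tolerance = 1e-8)
  }
})

test_that("ltt counts branches by manual enumeration on a 2-tip tree", {
  tr <- two_tip_tree()  # root 10 Ma, X extinct 4 Ma, Y extant
  expect_identical(lineages_at(tr, c(7, 3, 0)), c(2L, 1L, 1L))
  expect_identical(lineages_at(tr, 11), 0L)
  g <- time_grid(10, 1)
  expect_identical(ltt(tr, g), lineages_at(tr, g$mids))
})

test_that("ltt satisfies the conservation identity on simulated trees", {
  for (s in 1:25) {
    sim <- simulate_bd_tree(sim_config(12, 0.4, 0.2, seed = 100 + s,
                                       max_tips = 2000))
    tr <- sim$tree
    ages <- node_ages(tr)
    ntip <- ape::Ntip(tr)
    branchings <- ages[-seq_len(ntip)]
    extinctions <- ages[seq_len(ntip)][ages[seq_len(ntip)] > 0]
    g <- grid_for_tree(tr, 0.1)
    n <- ltt(tr, g)
    below_root <- g$mids < max(ages)
    pred <- vapply(g$mids, function(t)
      1 + sum(branchings > t) - sum(extinctions > t), numeric(1))
    expect_identical(n[below_root], as.integer(pred[below_root]))
    expect_identical(n[!below_root], rep(0L, sum(!below_root)))
    expect_identical(lineages_at(tr, 0), sum(ages[seq_len(ntip)] == 0))
  }
})

test_that("event rates follow their definition on a hand-checked tree", {
  tr <- two_tip_tree()  # root 10 Ma: branches X (10->4), Y (10->0)
  g <- time_grid(10, 5)  # bins (5,10] and (0,5]
  er <- event_rates(tr, g)
  # bin (5,10]: X alive 5 Myr + Y 5 Myr; bin (0,5]: X alive (4,5] + Y 5 Myr
  expect_equal(attr(er, "exposure"), c(10, 6))
  expect_equal(attr(er, "n_speciation"), c(1, 0))
  expect_equal(attr(er, "n_extinction"), c(0, 1))
  expect_equal(er$speciation[1, ], c(1 / 10, 0))
  expect_equal(er$extinction[1, ], c(0, 1 / 6))
  expect_equal(er$net, er$speciation - er$extinction)
})

test_that("pure-birth trees have identically zero extinction curves", {
  sim <- simulate_bd_tree(sim_config(8, 0.4, 0, seed = 23))
  er <- event_rates(sim$tree, grid_for_tree(sim$tree, 0.5))
  ext <- er$extinction[1, ]
  expect_true(all(ext[!is.na(ext)] == 0))
})

test_that("exposure-weighted mean rate equals total events over tree length", {
  for (s in c(3, 9, 27)) {
    sim <- simulate_bd_tree(sim_config(14, 0.3, 0.12, seed = s, max_tips = 2000))
    for (spacing in c(0.1, 0.7, 2)) {
      er <- event_rates(sim$tree, grid_for_tree(sim$tree, spacing))
      expo <- attr(er, "exposure")
      lam <- er$speciation[1, ]
      ok <- expo > 0
      expect_equal(sum(lam[ok] * expo[ok]) / sum(expo),
                   sim$tree$Nnode / sum(sim$tree$edge.length),
                   tolerance = 1e-9)
      expect_equal(sum(expo), sum(sim$tree$edge.length), tolerance = 1e-9)
    }
  }
})

test_that("event-rate estimates recover constant generating rates when pooled", {
  # lambda = 0.3, mu = 0.1; pool events and exposures over 50 trees
  tot_spec <- tot_ext <- tot_expo <- 0
  n_tips <- 0
  for (s in 1:50) {
    sim <- simulate_bd_tree(sim_config(12, 0.3, 0.1, seed = 5000 + s,
                                       max_tips = 3000))
    er <- event_rates(sim$tree, grid_for_tree(sim$tree, 0.5))
    tot_spec <- tot_spec + sum(attr(er, "n_speciation"))
    tot_ext <- tot_ext + sum(attr(er, "n_extinction"))
    tot_expo <- tot_expo + sum(attr(er, "exposure"))
    n_tips <- n_tips + ape::Ntip(sim$tree)
  }
  expect_gte(n_tips, 200)
  expect_lt(abs(tot_spec / tot_expo - 0.3) / 0.3, 0.15)
  expect_lt(abs(tot_ext / tot_expo - 0.1) / 0.1, 0.15)
})

test_that("partition ltt sums to the full ltt for habitat-pure clades", {
  # with habitat_transition_rate = 0 the root state is inherited everywhere,
  # so make a two-clade tree by grafting two single-habitat simulations
  s1 <- simulate_bd_tree(sim_config(10, 0.3, 0.1, seed = 41))
  s2 <- simulate_bd_tree(sim_config(10, 0.3, 0.1, seed = 43))
  t1 <- s1$tree; t2 <- s2$tree
  t1$root.edge <- NULL; t2$root.edge <- NULL
  t2$tip.label <- paste0("u", seq_len(ape::Ntip(t2)))
  r1 <- max(node_ages(t1)); r2 <- max(node_ages(t2))
  # graft the two crowns under a common root, stems chosen so both sets of
  # extant tips land at the same present
  stem1 <- 2 + max(r1, r2) - r1
  stem2 <- 2 + max(r1, r2) - r2
  txt <- sprintf("(%s:%f,%s:%f);",
                 sub(";$", "", ape::write.tree(t1)), stem1,
                 sub(";$", "", ape::write.tree(t2)), stem2)
  both <- ape::read.tree(text = txt)
  hab <- c(structure(rep("marine", ape::Ntip(t1)), names = t1$tip.label),
           structure(rep("terrestrial", ape::Ntip(t2)), names = t2$tip.label))
  g <- grid_for_tree(both, 0.1)
  n_all <- ltt(both, g)
  n_m <- ltt(extract_partition(both, hab, "marine"), g)
  n_t <- ltt(extract_partition(both, hab, "terrestrial"), g)
  inside <- g$mids < min(max(node_ages(t1)), max(node_ages(t2)))
  expect_identical(n_m[inside] + n_t[inside], n_all[inside])
})
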