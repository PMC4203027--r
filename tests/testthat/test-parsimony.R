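test_that("uniform tips need zero changes; simple 4-tip case needs one", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  rec0 <- parsimony_reconstruct(tr, c(A = "0", B = "0", C = "0", D = "0"))
  expect_identical(rec0$score, 0L)
  expect_true(all(vapply(rec0$mpr, identical, logical(1), "0")))

  # states (stable, unstable, stable, stable): one change, root stable
  st <- c(A = "stable", B = "unstable", C = "stable", D = "stable")
  rec1 <- parsimony_reconstruct(tr, st,
                                symbols = c("stable", "unstable"))
  expect_identical(rec1$score, 1L)
  root <- ape::Ntip(tr) + 1L
  expect_identical(rec1$mpr[[root]], "stable")
  # exhaustive enumeration confirms the minimum
  expect_identical(rec1$score,
                   as.integer(brute_force_score(tr, st,
                                                c("stable", "unstable"))))
})

test_that("Sankoff score equals brute force on random small trees", {
  set.seed(99)
  for (i in 1:150) {
    ntips <- sample(3:7, 1)
    tr <- random_rooted_tree(ntips)
    S <- sample(2:3, 1)
    symbols <- as.character(seq_len(S) - 1)
    st <- sample(c(symbols, "?"), ntips, replace = TRUE,
                 prob = c(rep(1, S), 0.3))
    names(st) <- tr$tip.label
    rec <- parsimony_reconstruct(tr, st, symbols = symbols)
    expect_identical(rec$score,
                     as.integer(brute_force_score(tr, st, symbols)))
  }
})

test_that("MPR sets contain exactly the states achieving the minimum", {
  set.seed(17)
  for (i in 1:25) {
    tr <- random_rooted_tree(5)
    symbols <- c("0", "1", "2")
    st <- sample(symbols, 5, replace = TRUE)
    names(st) <- tr$tip.label
    rec <- parsimony_reconstruct(tr, st, symbols = symbols)
    ntip <- ape::Ntip(tr)
    # oracle: force each internal node to each state by brute force
    edge <- tr$edge
    nnode <- tr$Nnode
    obs <- match(unname(st[tr$tip.label]), symbols)
    grid <- as.matrix(expand.grid(rep(list(seq_along(symbols)), nnode)))
    changes <- apply(grid, 1, function(g) {
      full <- c(obs, g)
      sum(full[edge[, 1]] != full[edge[, 2]])
    })
    for (nd in seq_len(nnode)) {
      achievable <- sort(unique(grid[changes == min(changes), nd]))
      expect_identical(rec$mpr[[ntip + nd]], symbols[achievable])
    }
  }
})

test_that("scores agree with phangorn and survive polytomies", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:30) {
    tr <- ape::rtree(8, br = NULL)
    # collapse one internal edge into a polytomy half the time
    if (i %% 2 == 0) tr <- ape::di2multi(ape::compute.brlen(tr), tol = 0.99)
    tr$edge.length <- NULL
    st <- sample(c("0", "1", "2"), ape::Ntip(tr), replace = TRUE)
    names(st) <- tr$tip.label
    rec <- parsimony_reconstruct(tr, st, symbols = c("0", "1", "2"))
    pd <- phangorn::phyDat(as.matrix(st), type = "USER",
                           levels = c("0", "1", "2"))
    expect_identical(rec$score,
                     as.integer(phangorn::parsimony(tr, pd,
                                                    method = "sankoff")))
  }
})

test_that("the score is invariant to root placement", {
  set.seed(55)
  for (i in 1:100) {
    tr <- random_rooted_tree(sample(4:8, 1))
    st <- sample(c("0", "1"), ape::Ntip(tr), replace = TRUE)
    names(st) <- tr$tip.label
    s1 <- parsimony_reconstruct(tr, st, symbols = c("0", "1"))$score
    out <- sample(tr$tip.label, 1)
    tr2 <- ape::root(ape::unroot(tr), outgroup = out, resolve.root = TRUE)
    s2 <- parsimony_reconstruct(tr2, st, symbols = c("0", "1"))$score
    expect_identical(s1, s2)
  }
})

test_that("reconstruction is invariant to tip-order permutation", {
  tr <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  st <- c(A = "0", B = "1", C = "0", D = "?", E = "1", F = "1")
  r1 <- parsimony_reconstruct(tr, st, symbols = c("0", "1"))
  r2 <- parsimony_reconstruct(tr, st[sample(names(st))],
                              symbols = c("0", "1"))
  expect_identical(r1$score, r2$score)
  expect_identical(r1$mpr, r2$mpr)
})

test_that("all-missing characters are fully ambiguous with score zero", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  st <- c(A = "?", B = "?", C = "?", D = "?")
  rec <- parsimony_reconstruct(tr, st, symbols = c("0", "1", "2"))
  expect_identical(rec$score, 0L)
  for (nd in seq_along(rec$mpr)) {
    expect_identical(rec$mpr[[nd]], c("0", "1", "2"))
  }
})

test_that("NEXUS inputs round-trip and mismatches are reported by name", {
  d <- quick_design()
  suite <- make_fixture_suite()
  est <- do.call(rbind, lapply(c("longtail", "shorttail"), function(nm) {
    g <- model_geometry(nm)
    estimate_derivatives(
      reduce_records(simulate_records(suite[[nm]], d, g, seed = 2), g))
  }))
  cm <- build_character_matrix(est)
  mpath <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(cm, mpath)
  tpath <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(ape::read.tree(text = "(longtail,shorttail);"),
                   file = tpath)  # uses a translate table
  inp <- read_nexus_inputs(tpath, mpath)
  expect_setequal(inp$tree$tip.label, cm$taxa)
  expect_identical(unname(inp$matrix["longtail", ]),
                   unname(aerophylo:::symbol_matrix(cm)["longtail", ]))

  # polytomies preserved through a NEXUS trees block
  poly <- fixture_tree()
  tp2 <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(poly, file = tp2)
  tr2 <- ape::read.nexus(tp2)
  expect_identical(tr2$Nnode, poly$Nnode)
  expect_lt(poly$Nnode, ape::Ntip(poly) - 1)  # non-binary: has a polytomy

  bad <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(ape::read.tree(text = "(longtail,missing_taxon);"),
                   file = bad)
  expect_error(read_nexus_inputs(bad, mpath), "missing_taxon")
})

test_that("mapping summary flips state at the configured transition node", {
  # basal taxa have an effective tail, derived taxa do not
  tr <- ape::read.tree(
    text = "(((b1,b2),b3),((d1,d2),(d3,d4)));")
  st <- c(b1 = "1", b2 = "1", b3 = "1",
          d1 = "0", d2 = "0", d3 = "0", d4 = "0")
  rec <- list(ctrl_pitch_taildorsi_15 =
                parsimony_reconstruct(tr, st, symbols = c("0", "1"),
                                      label = "ctrl_pitch_taildorsi_15"))
  rep_ <- summarize_mapping(rec, tr)
  ntip <- ape::Ntip(tr)
  basal_mrca <- ape::getMRCA(tr, c("b1", "b3"))
  derived_mrca <- ape::getMRCA(tr, c("d1", "d4"))
  expect_identical(rep_$states[rep_$node_number == basal_mrca], "1")
  expect_identical(rep_$states[rep_$node_number == derived_mrca], "0")
  expect_identical(rec[[1]]$score, 1L)

  expect_error(summarize_mapping(rec, tr, nodes = "nope"), "node")
  empty <- summarize_mapping(list(), tr)
  expect_identical(nrow(empty), 0L)
})
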