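test_that("core-gene threshold stays put when already under the cap", {
  set.seed(41)
  # ~500 of 5000 weights above Z=1 by construction of the normal
  u <- rnorm(5000)
  names(u) <- sprintf("g%04d", seq_along(u))
  res <- select_core_genes(u, max_genes = 1000)
  expect_equal(res$threshold, 1.0)
  expect_identical(res$genes, names(u)[res$z >= 1.0])
  expect_lt(length(res$genes), 1000)
})

test_that("threshold ratchets up by 0.05 until under the cap", {
  # three-level weight vector whose standardized scores sit at
  # (-0.351, 1.020, 3.092): 1200 genes exceed Z = 1.0 but only 900
  # exceed 1.05 (mid level solved so Z_mid = 1.02 exactly)
  u <- c(rep(0, 8800), rep(0.39822617, 300), rep(1, 900))
  z <- (u - mean(u)) / sd(u)
  expect_equal(sum(z >= 1.0), 1200)
  expect_equal(sum(z >= 1.05), 900)
  names(u) <- sprintf("g%04d", seq_along(u))
  res <- select_core_genes(u, z_init = 1.0, step = 0.05, max_genes = 1000)
  expect_equal(res$threshold, 1.05)
  expect_length(res$genes, 900)
})

test_that("identical weights give an empty core set with a warning", {
  u <- setNames(rep(2, 50), sprintf("g%d", 1:50))
  expect_warning(res <- select_core_genes(u), "constant")
  expect_length(res$genes, 0)
})

test_that("raising the threshold never increases the core-gene count", {
  set.seed(42)
  u <- setNames(rexp(2000), sprintf("g%d", 1:2000))
  sizes <- vapply(seq(1, 3, by = 0.25), function(th)
    length(select_core_genes(u, z_init = th, max_genes = 1e6)$genes), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("recurrence rate reproduces the worked containment example", {
  expect_equal(recurrence_rate(c("A", "B", "C", "D"),
                               list(c("A", "B", "X"),
                                    c("C", "D", "E", "F"))), 0.5)
  expect_equal(recurrence_rate(c("A", "B"), list(c("A", "B"))), 1.0)
  expect_equal(recurrence_rate(c("A", "B"), list(c("X", "Y"))), 0.0)
  expect_equal(recurrence_rate(c("A", "B"), list()), 0)
  expect_error(recurrence_rate(character(0), list(c("A"))), "empty")
})

test_that("recurrence rate equals a brute-force double loop", {
  set.seed(43)
  universe <- sprintf("g%02d", 1:30)
  for (rep in 1:60) {
    q <- sample(universe, sample(2:8, 1))
    others <- lapply(seq_len(sample(1:5, 1)), function(i)
      sample(universe, sample(2:8, 1)))
    best <- 0
    for (o in others) {
      inter <- 0
      for (g in q) if (g %in% o) inter <- inter + 1
      best <- max(best, inter / length(q))
    }
    expect_equal(recurrence_rate(q, others), best)
  }
})

test_that("containment is asymmetric", {
  a <- c("A", "B")
  b <- c("A", "B", "C", "D")
  expect_equal(recurrence_rate(a, list(b)), 1.0)
  expect_equal(recurrence_rate(b, list(a)), 0.5)
})

test_that("adding a shared gene cannot decrease the recurrence rate", {
  set.seed(44)
  universe <- sprintf("g%02d", 1:30)
  for (rep in 1:20) {
    q <- sample(universe, 5)
    others <- list(sample(universe, 8), sample(universe, 6))
    base <- recurrence_rate(q, others)
    best_other <- others[[which.max(vapply(others, function(o)
      length(intersect(q, o)) / length(q), 0))]]
    extra <- setdiff(best_other, q)
    if (length(extra) == 0) next
    grown <- c(q, extra[1])
    expect_gte(recurrence_rate(grown, others) * length(grown),
               base * length(q))
  }
})

test_that("stability filtering retains recurrent modules and applies the
           fallback for sparse cell types", {
  # module 'stable' identical in all 4 blocks -> aggregate 1.0
  # module 'lonely' appears once -> aggregate 0.0
  blocks <- lapply(1:4, function(b) {
    mods <- list(ct_stable = c("A", "B", "C", "D"))
    names(mods) <- sprintf("ct_%d_1", b)
    if (b == 1) mods[["ct_1_9"]] <- c("X", "Y", "Z")
    mods
  })
  rec <- stability_filter(blocks, threshold = 0.8)
  stable_ids <- rec$module_id[rec$stable]
  expect_length(stable_ids, 4)
  expect_false("ct_1_9" %in% stable_ids)
  expect_equal(rec$recurrence[rec$module_id == "ct_1_9"], 0)
  expect_error(stability_filter(blocks[1]), "single block")
})

test_that("fallback threshold rescues cell types with few stable modules", {
  # 2 blocks over disjoint gene pools: block-1 p-modules are fully
  # contained in their block-2 counterparts (containment 1), the
  # reverse containment is 4/8 = 0.5; q-modules recur at exactly 0.75
  P <- sprintf("p%02d", 1:12); Q <- sprintf("q%02d", 1:24)
  perfect <- lapply(1:3, function(i) P[(i * 4 - 3):(i * 4)])
  perfect_sup <- lapply(1:3, function(i)
    c(perfect[[i]], sprintf("extra%d_%d", i, 1:4)))
  partial_a <- lapply(1:6, function(i) Q[(i * 4 - 3):(i * 4)])
  partial_b <- lapply(1:6, function(i)
    c(partial_a[[i]][1:3], sprintf("novel%d", i)))
  b1 <- c(setNames(perfect, sprintf("ct_1_p%d", 1:3)),
          setNames(partial_a, sprintf("ct_1_q%d", 1:6)))
  b2 <- c(setNames(perfect_sup, sprintf("ct_2_p%d", 1:3)),
          setNames(partial_b, sprintf("ct_2_q%d", 1:6)))
  rec <- stability_filter(list(b1, b2), threshold = 0.8, fallback = 0.75,
                          fallback_min_modules = 5)
  # at 0.8 only the 3 block-1 p-modules pass (< 5), so 0.75 applies and
  # all twelve q-modules join them
  expect_equal(unique(rec$threshold_used), 0.75)
  expect_equal(sum(rec$stable), 15)
  expect_false(any(rec$stable[grepl("ct_2_p", rec$module_id)]))
})

test_that("near-duplicate stable modules collapse to one representative", {
  sets <- list(a = c("A", "B", "C", "D", "E"),
               b = c("A", "B", "C", "D"),      # contained in a
               c = c("X", "Y", "Z"))
  reps <- collapse_modules(sets, containment = 0.8)
  expect_length(reps, 2)
  members <- attr(reps, "members")
  expect_setequal(members[["a"]], c("a", "b"))
})
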