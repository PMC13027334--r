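make_cells <- function(n_donors = 10, cells_per_donor = 20, seed = 1) {
  set.seed(seed)
  donor <- rep(sprintf("d%02d", 1:n_donors), each = cells_per_donor)
  dx <- rep(rep(c("ASD", "Control"), length.out = n_donors),
            each = cells_per_donor)
  data.frame(cell_id = sprintf("c%03d", seq_along(donor)),
             donor = donor, diagnosis = dx, stringsAsFactors = FALSE)
}

test_that("donor splits are disjoint and near the target fraction", {
  cells <- make_cells()
  fracs <- sapply(1:25, function(s) {
    sp <- donor_split(cells, ratio = 0.7, seed = s)
    expect_length(intersect(sp$train_donors, sp$test_donors), 0)
    expect_length(intersect(sp$train, sp$test), 0)
    length(sp$train) / nrow(cells)
  })
  expect_lt(abs(mean(fracs) - 0.7), 0.1)
})

test_that("two donors split one per side; class coverage is enforced", {
  cells <- make_cells(n_donors = 2, cells_per_donor = 5)
  # with one donor per side, per-side class coverage is unsatisfiable
  sp <- donor_split(cells, ratio = 0.7, seed = 1,
                    require_both_classes = FALSE)
  expect_length(sp$train_donors, 1)
  expect_length(sp$test_donors, 1)
  # a single-class population can never satisfy coverage
  cells$diagnosis <- "ASD"
  expect_error(donor_split(cells, seed = 1), "cover both classes")
})

test_that("boosted model learns a planted separation and not noise", {
  set.seed(61)
  n <- 240; p <- 30
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:p)))
  labels <- rep(c("ASD", "Control"), each = n / 2)
  X[labels == "ASD", 1:10] <- X[labels == "ASD", 1:10] + 1.2
  tr <- c(1:84, 121:204); te <- setdiff(1:n, tr)
  m <- train_boosted(X[tr, ], labels[tr], boost_config(seed = 1),
                     X[te, ], labels[te])
  expect_gt(m$accuracy, 0.75)
  # chance level on permuted labels
  set.seed(62)
  perm <- sample(labels[tr])
  m0 <- train_boosted(X[tr, ], perm, boost_config(seed = 1),
                      X[te, ], labels[te])
  expect_lt(abs(m0$accuracy - 0.5), 0.15)
  expect_error(train_boosted(X[tr, ], rep("ASD", length(tr))),
               "single-class|exactly 2 levels")
})

test_that("duplicated feature columns leave predictions unchanged", {
  set.seed(63)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("g%d", 1:10)))
  labels <- rep(c("ASD", "Control"), each = n / 2)
  X[labels == "ASD", 1:3] <- X[labels == "ASD", 1:3] + 1
  tr <- 1:80; te <- 81:n
  m1 <- train_boosted(X[tr, ], labels[tr], boost_config(seed = 9),
                      X[te, ], labels[te])
  Xdup <- cbind(X, X)
  colnames(Xdup) <- sprintf("f%d", 1:20)
  m2 <- train_boosted(Xdup[tr, ], labels[tr], boost_config(seed = 9),
                      Xdup[te, ], labels[te])
  expect_identical(m1$predictions, m2$predictions)
})

test_that("fusion favours the informative view", {
  set.seed(64)
  n <- 200
  labels <- rep(c("ASD", "Control"), each = n / 2)
  sig <- matrix(rnorm(n * 20), n, 20)
  sig[labels == "ASD", 1:8] <- sig[labels == "ASD", 1:8] + 1.5
  noise <- matrix(rnorm(n * 20), n, 20)
  tr <- c(1:70, 101:170); te <- setdiff(1:n, tr)
  fm <- train_fusion(sig[tr, ], noise[tr, ], labels[tr],
                     sig[te, ], noise[te, ], labels[te], seed = 2)
  expect_gt(fm$beta["a"], fm$beta["b"])
  expect_gt(fm$accuracy, 0.7)
})

test_that("identical views share the contribution weight by symmetry", {
  set.seed(65)
  n <- 160
  labels <- rep(c("ASD", "Control"), each = n / 2)
  X <- matrix(rnorm(n * 15), n, 15)
  X[labels == "ASD", 1:5] <- X[labels == "ASD", 1:5] + 1
  fm <- train_fusion(X, X, labels, seed = 3)
  expect_equal(unname(fm$beta["a"]), 0.5, tolerance = 0.02)
  expect_equal(sum(fm$beta), 1)
})

test_that("test cells cannot influence training (leakage guard)", {
  set.seed(66)
  n <- 120
  labels <- rep(c("ASD", "Control"), each = n / 2)
  Xa <- matrix(rnorm(n * 10), n, 10)
  Xa[labels == "ASD", 1:4] <- Xa[labels == "ASD", 1:4] + 1
  Xb <- matrix(rnorm(n * 10), n, 10)
  te1 <- matrix(rnorm(40 * 10), 40, 10)
  te2 <- te1 + 100                          # radically different test set
  f1 <- train_fusion(Xa, Xb, labels, te1, te1, rep(c("ASD", "Control"), 20),
                     seed = 4)
  f2 <- train_fusion(Xa, Xb, labels, te2, te2, rep(c("ASD", "Control"), 20),
                     seed = 4)
  expect_identical(f1$beta, f2$beta)        # beta fit on training only
  expect_error(train_fusion(Xa[1:50, ], Xb, labels), "nrow")
})

test_that("misaligned view rownames are an explicit error", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("c%d", 1:10), NULL))
  Y <- X; rownames(Y) <- rev(rownames(X))
  expect_error(train_fusion(X, Y, rep(c("ASD", "Control"), 5)),
               "not aligned")
})
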