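nocap <- match_config(search_radius = NULL)

test_that("identical descriptor sets self-match with kappa 0", {
  set.seed(11)
  A <- matrix(runif(10 * 192, 0, 5), 10, 192)
  da <- make_desc(A); db <- make_desc(A)
  m <- match_forward(da, db, nocap)
  expect_equal(nrow(m), 10L)
  expect_equal(m$target, m$template)
  expect_true(all(m$S1 == 0))
  expect_true(all(m$kappa == 0))
  surv <- bidirectional_filter(m, da, db, nocap)
  expect_equal(nrow(surv), 10L)
})

test_that("the ratio test accepts 1:4 and rejects 3:4 distance pairs", {
  q <- matrix(0, 1, 192)
  t1 <- matrix(0, 2, 192); t1[1, 1] <- 1; t1[2, 1] <- 2      # S = 1, 4
  m <- match_forward(make_desc(q), make_desc(t1), nocap)
  expect_equal(nrow(m), 1L)
  expect_equal(m$S1, 1); expect_equal(m$S2, 4); expect_equal(m$kappa, 0.25)
  expect_equal(m$target, 1L)

  t2 <- matrix(0, 2, 192); t2[1, 1] <- sqrt(3); t2[2, 1] <- 2  # S = 3, 4
  m2 <- match_forward(make_desc(q), make_desc(t2), nocap)
  expect_equal(nrow(m2), 0L)
})

test_that("matching equals the exhaustive double-loop oracle", {
  set.seed(12)
  for (rep in 1:3) {
    A <- matrix(runif(8 * 192, 0, 2), 8, 192)
    B <- matrix(runif(12 * 192, 0, 2), 12, 192)
    da <- make_desc(A); db <- make_desc(B)
    got <- match_forward(da, db, nocap)
    bp <- attr(db, "points")
    ref <- naive_match(A, B, order(order(bp$i, bp$j, bp$k)), 0.5)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$template, ref$template)
      expect_equal(got$target, ref$target)
      expect_all_near(got$S1, ref$S1, 1e-9)
      expect_all_near(got$S2, ref$S2, 1e-9)
      expect_all_near(got$kappa, ref$kappa, 1e-9)
    }
  }
})

test_that("lowering the kappa threshold never adds matches", {
  set.seed(13)
  A <- matrix(runif(20 * 192), 20, 192)
  B <- matrix(runif(20 * 192), 20, 192)
  da <- make_desc(A); db <- make_desc(B)
  n_prev <- Inf
  for (thr in c(0.9, 0.6, 0.3, 0.1)) {
    n <- nrow(match_forward(da, db, match_config(kappa_threshold = thr,
                                                 search_radius = NULL)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("bidirectional filter deletes one-to-many claims", {
  # p1 and p2 both prefer t1; t1's reverse best is p1
  tmpl <- matrix(0, 2, 192); tmpl[1, 1] <- 0; tmpl[2, 1] <- 4
  targ <- matrix(0, 2, 192); targ[1, 1] <- 1; targ[2, 1] <- 9
  dt <- make_desc(tmpl); dg <- make_desc(targ)
  fwd <- match_forward(dt, dg, nocap)
  expect_equal(nrow(fwd), 2L)
  expect_equal(fwd$target, c(1L, 1L))
  surv <- bidirectional_filter(fwd, dt, dg, nocap)
  expect_equal(nrow(surv), 1L)
  expect_equal(surv$template, 1L)
  expect_equal(surv$target, 1L)
})

test_that("bidirectional filtering is a subset operation and idempotent", {
  set.seed(14)
  A <- matrix(runif(30 * 192, 0, 2), 30, 192)
  B <- A + matrix(rnorm(30 * 192, sd = 0.05), 30, 192)
  da <- make_desc(A); db <- make_desc(B)
  fwd <- match_forward(da, db, nocap)
  s1 <- bidirectional_filter(fwd, da, db, nocap)
  expect_true(all(paste(s1$template, s1$target) %in%
                  paste(fwd$template, fwd$target)))
  s2 <- bidirectional_filter(s1, da, db, nocap)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(any(duplicated(s1$target)))
})

test_that("the search radius restricts candidates", {
  set.seed(15)
  A <- matrix(runif(6 * 192), 6, 192)
  coords <- cbind(c(0, 10, 20, 100, 110, 120), 0, 0)
  da <- make_desc(A, coords = coords)
  db <- make_desc(A, coords = coords)
  m <- suppressMessages(match_forward(da, db, match_config(search_radius = 25)))
  # self-matches still found: each point has >= 2 candidates within 25 mm
  expect_equal(m$template, m$target)
  expect_true(all(abs(coords[m$template, 1] - coords[m$target, 1]) <= 25))
})

test_that("matches_to_landmarks preserves order and pairing", {
  set.seed(16)
  A <- matrix(runif(5 * 192), 5, 192)
  da <- make_desc(A); db <- make_desc(A)
  m <- match_forward(da, db, nocap)
  lms <- matches_to_landmarks(m)
  expect_equal(nrow(lms$template), nrow(m))
  expect_equal(lms$template$x, m$tx)
  expect_equal(lms$target$x, m$gx)
  expect_identical(lms$template$label, lms$target$label)
  empty <- m[0, ]
  expect_error(matches_to_landmarks(empty), "relax")
})

test_that("degenerate distances are handled deterministically", {
  # three identical targets: S1 = S2 = 0 -> kappa defined as 0, lex winner
  q <- matrix(1, 1, 192)
  targ <- matrix(1, 3, 192)
  m <- match_forward(make_desc(q), make_desc(targ), nocap)
  expect_equal(nrow(m), 1L)
  expect_equal(m$kappa, 0)
  expect_equal(m$target, 1L)
  expect_error(match_forward(make_desc(q), make_desc(targ[0, , drop = FALSE]),
                             nocap), "empty")
})
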