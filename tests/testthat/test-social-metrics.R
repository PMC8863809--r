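test_that("CRI matches direct substitution into its formula", {
  # G = 10, R = 5, A = 1 plain aggression, T = 100 -> (10 + 5 - 5)/100
  log1 <- make_log(list(
    list(1, "F", "J", "groom", 10),
    list(1, "J", "F", "prox5m", 5),
    list(1, "F", "J", "aggression", 1)),
    c(F = 100, J = 100))
  cri <- compute_cri(log1, "F")
  expect_equal(cri$cri[cri$partner == "J"], 0.10)

  # one severe aggression counts double: (4 + 6 - 5*2)/50 = 0
  log2 <- make_log(list(
    list(1, "F", "J", "groom", 4),
    list(1, "F", "J", "prox5m", 6),
    list(1, "J", "F", "severe", 1)),
    c(F = 50, J = 50))
  cri2 <- compute_cri(log2, "F")
  expect_equal(cri2$cri[cri2$partner == "J"], 0)
})

test_that("CRI equals a naive re-count over raw records", {
  set.seed(17)
  subjects <- c("A", "B", "C", "D")
  kinds <- c("groom", "prox5m", "aggression", "chase", "threat", "severe",
             "pantgrunt")
  recs <- lapply(1:120, function(i) {
    ab <- sample(subjects, 2)
    list(sample(1:6, 1), ab[1], ab[2], sample(kinds, 1), sample(1:4, 1))
  })
  log <- make_log(recs, c(A = 200, B = 200, C = 200, D = 200))
  cri <- compute_cri(log, "A")
  df <- log$records
  for (j in c("B", "C", "D")) {
    dy <- df[(df$actor == "A" & df$receiver == j) |
               (df$actor == j & df$receiver == "A"), ]
    G <- sum(dy$count[dy$kind == "groom"])
    R <- sum(dy$count[dy$kind == "prox5m"])
    A <- sum(dy$count[dy$kind %in% c("aggression", "chase", "threat")]) +
      2 * sum(dy$count[dy$kind == "severe"])
    expect_equal(cri$cri[cri$partner == j], (G + R - 5 * A) / 200)
  }
})

test_that("CRI is invariant under doubling all tallies", {
  log1 <- make_log(list(
    list(1, "F", "J", "groom", 3),
    list(1, "F", "J", "prox5m", 2),
    list(1, "F", "J", "chase", 1)),
    c(F = 80, J = 80))
  log2 <- make_log(list(
    list(1, "F", "J", "groom", 6),
    list(1, "F", "J", "prox5m", 4),
    list(1, "F", "J", "chase", 2)),
    c(F = 160, J = 160))
  expect_equal(compute_cri(log1, "F")$cri, compute_cri(log2, "F")$cri)
})

test_that("zero focal effort is an error", {
  log <- make_log(list(list(1, "F", "J", "groom", 1)), c(F = 0, J = 10))
  expect_error(compute_cri(log, "F"), "positive")
})

test_that("bond partners are top-3 positive, non-bonds bottom-3 negative", {
  cri <- data.frame(partner = c("P1", "P2", "P3", "P4", "P5"),
                    cri = c(0.3, 0.2, 0.1, 0.05, -0.1))
  sel <- select_bond_partners(cri)
  expect_equal(sel$bond, c("P1", "P2", "P3"))
  expect_equal(sel$non_bond, "P5")
  expect_length(intersect(sel$bond, sel$non_bond), 0)

  all_neg <- data.frame(partner = c("P1", "P2"), cri = c(-0.2, -0.4))
  sel2 <- select_bond_partners(all_neg)
  expect_length(sel2$bond, 0)
  expect_equal(sel2$non_bond, c("P2", "P1"))
})

test_that("planted bond partners are recovered from generated logs", {
  hits <- vapply(1:10, function(sd) {
    ds <- generate_dataset(generator_config(seed = sd, n_events_per_type = 1,
                                            n_baseline_events = 1))
    cri <- cri_matrix(ds$interactions)
    mean(vapply(names(ds$truth$bond_partners), function(f) {
      sel <- select_bond_partners(cri[cri$focal == f, c("partner", "cri")],
                                  ds$interactions, f)
      mean(ds$truth$bond_partners[[f]] %in% sel$bond)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("an even match transfers exactly k/2 rating points", {
  log <- make_log(list(list(1, "W", "L", "chase", 1)), c(W = 10, L = 10))
  elo <- compute_elo(log, k_factor = 100, start_rating = 1000)
  r <- elo$ratings
  expect_equal(r$final_elo[r$subject_id == "W"], 1050)
  expect_equal(r$final_elo[r$subject_id == "L"], 950)
})

test_that("pant-grunts award the receiver and rating mass is conserved", {
  log <- make_log(list(
    list(1, "S", "D", "pantgrunt", 2),
    list(2, "D", "S", "threat", 1)),
    c(S = 10, D = 10))
  elo <- compute_elo(log, k_factor = 100, start_rating = 1000)
  r <- elo$ratings
  expect_gt(r$final_elo[r$subject_id == "D"], r$final_elo[r$subject_id == "S"])
  expect_equal(sum(r$final_elo), 2 * 1000)
})

test_that("rating mass is conserved after every update on a random log", {
  set.seed(31)
  ds <- small_dataset(seed = 31)
  elo <- suppressWarnings(compute_elo(ds$interactions))
  n <- nrow(elo$ratings)
  expect_equal(sum(elo$ratings$final_elo), n * 1000, tolerance = 1e-9)
  # winner gain always equals loser loss
  expect_true(all(elo$history$delta > 0))
})

test_that("standardized scores are invariant to the start rating", {
  ds <- small_dataset(seed = 8)
  e1 <- suppressWarnings(compute_elo(ds$interactions, start_rating = 1000))
  e2 <- suppressWarnings(compute_elo(ds$interactions, start_rating = 0))
  expect_equal(e1$ratings$z_elo, e2$ratings$z_elo, tolerance = 1e-9)
  expect_equal(mean(e1$ratings$z_elo), 0, tolerance = 1e-12)
  expect_equal(sd(e1$ratings$z_elo), 1, tolerance = 1e-12)
})

test_that("a strict planted hierarchy is recovered exactly", {
  for (sd in 1:5) {
    cfg <- generator_config(seed = sd, n_events_per_type = 1,
                            n_baseline_events = 1,
                            hierarchy_steepness = 50, agonistic_rate = 4)
    ds <- generate_dataset(cfg)
    elo <- suppressWarnings(compute_elo(ds$interactions))
    est <- elo$ratings$subject_id[order(-elo$ratings$final_elo)]
    expect_identical(est, ds$truth$elo_order)
  }
})

test_that("hierarchy stability is high under a stable planted hierarchy", {
  ds <- generate_dataset(generator_config(seed = 4, n_events_per_type = 1,
                                          n_baseline_events = 1))
  stab <- elo_stability(ds$interactions)
  expect_gte(stab$rank_correlation, 0.8)
})
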