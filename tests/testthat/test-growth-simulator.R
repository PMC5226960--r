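test_that("leaf emission follows the floor of rate times cumulative GDD", {
  tt <- season_fixture()  # ~2278 GDD over 169 days
  p0 <- genotype_params(0, 2, 25, 0.3)
  sch0 <- leaf_emission_schedule(p0, tt)
  expect_equal(nrow(sch0), 8)
  expect_true(all(sch0$preformed))
  expect_true(all(sch0$emergence_day == 0))

  p <- genotype_params(0.033, 2, 25, 0.3)
  sch <- leaf_emission_schedule(p, tt)
  expect_equal(nrow(sch), 8 + floor(0.033 * tt$cumulative[length(tt$tt_d)]))
  expect_equal(sum(!sch$preformed), 75)  # floor(0.033 * 2278) at ~2278 GDD
  expect_true(!is.unsorted(sch$emergence_day))
})

test_that("one leaf roughly every three days at 10 GDD/day and 0.033 leaves/GDD", {
  tt <- flat_tt(10, 120)
  p <- genotype_params(0.033, 2, 25, 0)
  sch <- leaf_emission_schedule(p, tt)
  gaps <- diff(sch$emergence_day[!sch$preformed])
  expect_lt(abs(mean(gaps) - 1 / 0.33), 0.25)
})

test_that("daily leaf-emergence rate is the product of rate and daily GDD", {
  tt <- flat_tt(15, 10)
  p <- genotype_params(0.033, 2, 25, 0.3)
  expect_equal(rle_series(p, tt), rep(0.495, 10))
  expect_equal(rle_series(p, thermal_time_series(rep(0, 5))), rep(0, 5))
  # conservation: integrated rate matches the neoformed count up to floor
  tt2 <- season_fixture()
  expect_lt(abs(sum(rle_series(p, tt2)) - sum(!leaf_emission_schedule(p, tt2)$preformed)),
            1)
})

test_that("sylleptic probability is the clipped linear form in mean RLE", {
  a <- exp(-1.25)
  expect_equal(sylleptic_probability(a, rep(1 / 3, 7)), a / 3)
  expect_equal(sylleptic_probability(a, rep(0, 7)), 0)
  expect_equal(sylleptic_probability(10, rep(1, 7)), 1)  # clipped
  expect_error(sylleptic_probability(-1, rep(1, 7)), "nonnegative")
  expect_error(sylleptic_probability(a, rep(1, 5), n_days = 7), "n_days")
})

test_that("degenerate parameters give degenerate trees", {
  tt <- season_fixture()
  no_branch <- simulate_tree(genotype_params(0.033, 2, 25, 0), tt = tt, seed = 3)
  expect_equal(no_branch$nb_syll, 0)
  no_growth <- simulate_tree(genotype_params(0, 2, 25, 0.5), tt = tt, seed = 3)
  expect_equal(no_growth$nb_leaves, 8)
  expect_equal(no_growth$nb_syll, 0)
})

test_that("identical parameters, climate and seed give identical trees", {
  tt <- season_fixture()
  p <- genotype_params(0.033, 2.02, 25.54, exp(-1.25))
  t1 <- simulate_tree(p, branching_params(), tt, seed = 11)
  t2 <- simulate_tree(p, branching_params(), tt, seed = 11)
  expect_identical(t1, t2)
})

test_that("tree bookkeeping identities hold exactly", {
  tt <- season_fixture()
  p <- genotype_params(0.033, 2.02, 25.54, exp(-1.25))
  tr <- simulate_tree(p, branching_params(), tt, seed = 4, preformed_scale = 0.5)
  m <- tr$metamers
  expect_equal(tr$nb_leaves, nrow(m))
  expect_equal(tr$nb_syll, sum(m$sylleptic))
  expect_equal(tr$trunk_length,
               sum(!m$preformed) * 2.02 + 8 * 2.02 * 0.5)
  # leaf count nondecreasing in the emergence rate
  nl <- sapply(c(0.01, 0.02, 0.033, 0.05), function(r)
    simulate_tree(genotype_params(r, 2, 25, 0), tt = tt, seed = 1)$nb_leaves)
  expect_true(all(diff(nl) >= 0))
})

test_that("Monte-Carlo mean sylleptic count matches the analytic expectation", {
  tt <- season_fixture()
  p <- genotype_params(0.033, 2.02, 25.54, exp(-1.25))
  br <- branching_params()
  # independent oracle: walk the deterministic schedule and sum the
  # per-eligibility-event probabilities
  sch <- leaf_emission_schedule(p, tt)
  rle_d <- p$rle_gdd * tt$tt_d
  neo <- sch[!sch$preformed, ]
  exp_syll <- 0
  seen <- integer(0)
  for (i in seq_len(nrow(neo))) {
    node <- neo$rank[i] - br$r_k
    if (node >= 1 && !(node %in% seen)) {
      seen <- c(seen, node)
      d <- neo$emergence_day[i]
      idx <- max(1, d - br$n_days + 1):d
      wm <- sum(rle_d[idx]) / br$n_days
      exp_syll <- exp_syll + min(1, p$a_syll * wm)
    }
  }
  ns <- vapply(1:1000, function(s) simulate_tree(p, br, tt, seed = s)$nb_syll, 0)
  mc_se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - exp_syll), 3 * mc_se)
  expect_equal(expected_nb_syll(p, br, tt), exp_syll)
})

test_that("population runs are seeded per tree and summarised per genotype", {
  tt <- season_fixture()
  ptab <- data.frame(genotype_id = c("A", "B", "C", "D"),
                     rle_gdd = 0.033, in_length = 2.02, leaf_area = 25.54,
                     a_syll = exp(-1.25))
  pop <- simulate_population(ptab, branching_params(), tt, n_reps = 5, seed = 9)
  expect_length(pop$trees, 20)
  expect_equal(nrow(pop$summary), 4)
  # first tree reproduces a direct single-tree run under the derived seed
  direct <- simulate_tree(genotype_params(0.033, 2.02, 25.54, exp(-1.25), "A"),
                          branching_params(), tt, seed = 9 + 1)
  expect_identical(pop$trees[[1]]$metamers, direct$metamers)
  expect_error(simulate_population(ptab[c(1, 1), ], branching_params(), tt),
               "duplicate")
})

test_that("identical genotypes differ only by binomial sampling of laterals", {
  tt <- season_fixture()
  ptab <- data.frame(genotype_id = sprintf("G%02d", 1:40),
                     rle_gdd = 0.033, in_length = 2.02, leaf_area = 25.54,
                     a_syll = exp(-1.25))
  pop <- simulate_population(ptab, branching_params(), tt, n_reps = 5, seed = 21)
  expect_equal(var(pop$summary$nb_leaves), 0)
  expect_equal(var(pop$summary$trunk_length), 0)
  # variance of genotype means of nb_syll ~ total Bernoulli variance / reps
  p <- genotype_params(0.033, 2.02, 25.54, exp(-1.25))
  sch <- leaf_emission_schedule(p, tt)
  rle_d <- p$rle_gdd * tt$tt_d
  neo <- sch[!sch$preformed, ]
  v <- 0
  for (i in seq_len(nrow(neo))) {
    if (neo$rank[i] - 20 >= 1) {
      d <- neo$emergence_day[i]
      pr <- min(1, p$a_syll * sum(rle_d[max(1, d - 6):d]) / 7)
      v <- v + pr * (1 - pr)
    }
  }
  expect_lt(abs(var(pop$summary$nb_syll) - v / 5), 3 * (v / 5) / sqrt(39 / 2))
})

test_that("sylleptic frequency profile integrates back to the mean count", {
  tt <- season_fixture()
  ptab <- data.frame(genotype_id = sprintf("G%02d", 1:20),
                     rle_gdd = seq(0.025, 0.04, length.out = 20),
                     in_length = 2.02, leaf_area = 25.54, a_syll = exp(-1.25))
  pop <- simulate_population(ptab, branching_params(), tt, n_reps = 3, seed = 5)
  max_rank <- max(vapply(pop$trees, `[[`, 0, "nb_leaves"))
  prof <- sylleptic_distribution(pop, max_rank)
  total <- sum(prof$freq * prof$n_trees)
  expect_equal(total / length(pop$trees), mean(vapply(pop$trees, `[[`, 0, "nb_syll")))
  # each tree's last r_k ranks never fall below the apex and are never tested
  for (tr in pop$trees) {
    m <- tr$metamers
    expect_false(any(m$sylleptic[m$rank > tr$nb_leaves - 20]))
  }
  # no-branching population gives an all-zero profile
  ptab0 <- ptab; ptab0$a_syll <- 0
  pop0 <- simulate_population(ptab0, branching_params(), tt, n_reps = 2, seed = 1)
  expect_true(all(sylleptic_distribution(pop0, 50)$freq == 0))
  expect_error(sylleptic_distribution(list(), 10), "nonempty")
  expect_error(sylleptic_distribution(pop, 0), "max_rank")
})

test_that("tree exports write metamer CSV and minimal MTG topology", {
  tt <- season_fixture()
  tr <- simulate_tree(genotype_params(0.033, 2, 25, exp(-1.25)), tt = tt, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tree_csv(tr, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), tr$nb_leaves)
  mtg <- withr::local_tempfile(fileext = ".mtg")
  write_mtg(tr, mtg)
  lines <- readLines(mtg)
  expect_true(any(grepl("^/T1$", lines)))
  expect_equal(sum(grepl("\\+S1", lines)), tr$nb_syll)
  expect_equal(sum(grepl("M[0-9]+", lines[-seq_len(16)])), tr$nb_leaves)
})
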