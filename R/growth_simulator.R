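# First-year trunk development: phytomer emission from accumulated thermal
# time, organ dimensions, and stochastic sylleptic lateral emergence whose
# daily probability is linear in the recent leaf-emergence rate.

#' Per-genotype simulator parameters
#'
#' The four parameters driving primary growth and branching of a first-year
#' tree: the leaf emergence rate per growing degree-day, the final length of
#' an individual internode, the final area of an individual leaf, and the
#' coefficient linking sylleptic emergence probability to the recent mean
#' leaf-emergence rate.
#'
#' @param rle_gdd leaf emergence rate (leaves per GDD), > 0 (0 allowed for
#'   degenerate no-growth cases).
#' @param in_length internode length (cm), > 0.
#' @param leaf_area individual leaf area (cm2), > 0.
#' @param a_syll sylleptic branching coefficient (probability per unit
#'   leaves/day), >= 0.
#' @param genotype_id identifier, any scalar.
#' @return An object of class `genotype_params`.
#' @export
genotype_params <- function(rle_gdd, in_length, leaf_area, a_syll,
                            genotype_id = "G1") {
  if (rle_gdd < 0) stop("rle_gdd must be nonnegative")
  if (in_length <= 0) stop("in_length must be positive")
  if (leaf_area <= 0) stop("leaf_area must be positive")
  if (a_syll < 0) stop("a_syll must be nonnegative")
  structure(list(rle_gdd = rle_gdd, in_length = in_length,
                 leaf_area = leaf_area, a_syll = a_syll,
                 genotype_id = genotype_id),
            class = "genotype_params")
}

#' Branching-rule parameters
#'
#' A node becomes testable for sylleptic emergence only once it sits `r_k`
#' ranks below the terminal apex, representing apical inhibition of axillary
#' buds; the emergence probability uses the mean leaf-emergence rate over the
#' `n_days` days up to and including the test day. Defaults (20, 7) are the
#' combination retained by grid search on the pooled sylleptic profile.
#'
#' @param r_k integer >= 1, rank offset below the apex.
#' @param n_days integer >= 1, length of the averaging window (days).
#' @return An object of class `branching_params`.
#' @export
branching_params <- function(r_k = 20L, n_days = 7L) {
  r_k <- as.integer(r_k); n_days <- as.integer(n_days)
  if (r_k < 1) stop("r_k must be >= 1")
  if (n_days < 1) stop("n_days must be >= 1")
  structure(list(r_k = r_k, n_days = n_days), class = "branching_params")
}

#' Deterministic leaf emission schedule
#'
#' The first `n_preformed` metamers are preformed in the bud and present at
#' budburst (emergence day 0). Neoformed metamers appear as the floor of
#' `rle_gdd` times cumulative thermal time increments: the neoformed count at
#' day d is `floor(rle_gdd * cumulative_tt[d])`, and new ranks are appended
#' on the day the floor increments (several on one day is possible).
#'
#' @param params a [genotype_params()].
#' @param tt a `thermal_time_series` covering the season.
#' @param n_preformed number of preformed metamers (default 8).
#' @return data frame with columns `rank`, `emergence_day` (0 = budburst,
#'   then season-day index), `preformed`.
#' @export
leaf_emission_schedule <- function(params, tt, n_preformed = 8L) {
  if (params$rle_gdd < 0) stop("rle_gdd must be nonnegative")
  n_preformed <- as.integer(n_preformed)
  neo_count <- floor(params$rle_gdd * tt$cumulative)
  new_per_day <- diff(c(0, neo_count))
  days <- rep(seq_along(tt$tt_d), new_per_day)
  n_neo <- length(days)
  data.frame(
    rank = seq_len(n_preformed + n_neo),
    emergence_day = c(rep(0L, n_preformed), days),
    preformed = c(rep(TRUE, n_preformed), rep(FALSE, n_neo))
  )
}

#' Daily leaf-emergence-rate series
#'
#' `rle_d[d] = rle_gdd * tt_d[d]`, in leaves per day.
#'
#' @inheritParams leaf_emission_schedule
#' @return numeric vector, one value per season day.
#' @export
rle_series <- function(params, tt) {
  params$rle_gdd * tt$tt_d
}

#' Sylleptic emergence probability
#'
#' The daily probability that a testable node produces a sylleptic lateral:
#' the branching coefficient times the mean leaf-emergence rate over the
#' averaging window, clipped to `[0, 1]` (the linear form itself is
#' unbounded).
#'
#' @param a_syll branching coefficient, >= 0.
#' @param rle_window the `n_days` leaf-emergence-rate values (leaves/day) of
#'   the days up to and including the test day.
#' @param n_days window length; must equal `length(rle_window)`.
#' @return a probability in `[0, 1]`.
#' @export
sylleptic_probability <- function(a_syll, rle_window, n_days = length(rle_window)) {
  if (a_syll < 0) stop("a_syll must be nonnegative")
  if (length(rle_window) != n_days) {
    stop("rle_window must hold exactly n_days values")
  }
  p <- a_syll * sum(rle_window) / n_days
  min(max(p, 0), 1)
}

# Window mean of a daily series at day d: the n_days values at indices
# d - n_days + 1 .. d, padding days before the season start with zero
# (no pre-budburst growth).
.window_values <- function(x, d, n_days) {
  idx <- (d - n_days + 1L):d
  vals <- numeric(n_days)
  ok <- idx >= 1L
  vals[ok] <- x[idx[ok]]
  vals
}

#' Simulate one first-year tree
#'
#' Runs the deterministic emission schedule, then, on the day the metamer of
#' rank `k` is emitted and provided `k - r_k >= 1`, subjects the node at rank
#' `k - r_k` to exactly one Bernoulli trial with the day's sylleptic
#' probability. Nodes are tested at most once; nodes that never fall `r_k`
#' ranks below the final apex are never tested. Organ dimensions are applied
#' at their final values (organ expansion dynamics do not affect the final
#' architecture and are omitted).
#'
#' @param params a [genotype_params()].
#' @param branching a [branching_params()].
#' @param tt a `thermal_time_series`.
#' @param seed integer RNG seed for the Bernoulli draws.
#' @param n_preformed preformed metamer count (default 8).
#' @param preformed_scale scale factor applied to preformed organ dimensions
#'   (default 1).
#' @return An object of class `simulated_tree`: list with `metamers` (data
#'   frame: rank, emergence_day, preformed, sylleptic, internode_length,
#'   leaf_area), `nb_leaves`, `trunk_length`, `nb_syll`, `rng_seed`.
#' @export
simulate_tree <- function(params, branching = branching_params(), tt,
                          seed = 1L, n_preformed = 8L, preformed_scale = 1) {
  sched <- leaf_emission_schedule(params, tt, n_preformed)
  rle_d <- rle_series(params, tt)
  n_met <- nrow(sched)
  sylleptic <- rep(FALSE, n_met)
  tested <- rep(FALSE, n_met)
  set.seed(seed)
  neo <- sched[!sched$preformed, , drop = FALSE]
  if (nrow(neo) > 0 && params$a_syll > 0) {
    p_day <- rep(NA_real_, length(tt$tt_d))
    for (i in seq_len(nrow(neo))) {
      k <- neo$rank[i]
      target <- k - branching$r_k
      if (target >= 1L && !tested[target]) {
        d <- neo$emergence_day[i]
        if (is.na(p_day[d])) {
          p_day[d] <- sylleptic_probability(
            params$a_syll, .window_values(rle_d, d, branching$n_days),
            branching$n_days)
        }
        tested[target] <- TRUE
        sylleptic[target] <- stats::runif(1) < p_day[d]
      }
    }
  }
  in_len <- ifelse(sched$preformed, params$in_length * preformed_scale,
                   params$in_length)
  la <- ifelse(sched$preformed, params$leaf_area * preformed_scale,
               params$leaf_area)
  metamers <- data.frame(
    rank = sched$rank, emergence_day = sched$emergence_day,
    preformed = sched$preformed, sylleptic = sylleptic,
    internode_length = in_len, leaf_area = la
  )
  structure(list(
    metamers = metamers,
    nb_leaves = n_met,
    trunk_length = sum(in_len),
    nb_syll = sum(sylleptic),
    genotype_id = params$genotype_id,
    rng_seed = seed
  ), class = "simulated_tree")
}

#' @export
print.simulated_tree <- function(x, ...) {
  cat("<simulated_tree> genotype ", format(x$genotype_id), ": ",
      x$nb_leaves, " leaves, trunk ", round(x$trunk_length, 1), " cm, ",
      x$nb_syll, " sylleptic lateral(s)\n", sep = "")
  invisible(x)
}

#' Expected number of sylleptic laterals
#'
#' Analytic expectation of `nb_syll` under the Bernoulli construction: the
#' sum, over nodes that become testable, of the emergence probability on
#' their test day. The emission schedule is deterministic, so this is exact.
#'
#' @inheritParams simulate_tree
#' @return expected count (numeric scalar).
#' @export
expected_nb_syll <- function(params, branching = branching_params(), tt,
                             n_preformed = 8L) {
  sched <- leaf_emission_schedule(params, tt, n_preformed)
  rle_d <- rle_series(params, tt)
  neo <- sched[!sched$preformed, , drop = FALSE]
  tested <- rep(FALSE, nrow(sched))
  total <- 0
  for (i in seq_len(nrow(neo))) {
    target <- neo$rank[i] - branching$r_k
    if (target >= 1L && !tested[target]) {
      tested[target] <- TRUE
      d <- neo$emergence_day[i]
      total <- total + sylleptic_probability(
        params$a_syll, .window_values(rle_d, d, branching$n_days),
        branching$n_days)
    }
  }
  total
}

#' Simulate a population of trees
#'
#' Runs `n_reps` independent replicate trees per genotype. Per-tree seeds
#' are derived from the master seed with a counter, so runs are reproducible
#' and independent of evaluation order. The per-genotype `nb_syll` reported
#' in the summary is the mean over replicates (default 5 replicates, as the
#' sylleptic process is stochastic).
#'
#' @param param_table a data frame with columns `genotype_id`, `rle_gdd`,
#'   `in_length`, `leaf_area`, `a_syll` (one row per genotype), or a list of
#'   [genotype_params()].
#' @param branching a [branching_params()].
#' @param tt a `thermal_time_series`.
#' @param n_reps replicate simulations per genotype (>= 1).
#' @param seed master seed.
#' @param ... passed to [simulate_tree()].
#' @return An object of class `simulated_population`: list with `trees`
#'   (list of `simulated_tree`), and `summary` (data frame of per-genotype
#'   means of nb_leaves, trunk_length, nb_syll).
#' @export
simulate_population <- function(param_table, branching = branching_params(),
                                tt, n_reps = 5L, seed = 1L, ...) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  plist <- .as_param_list(param_table)
  ids <- vapply(plist, function(p) as.character(p$genotype_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate genotype ids in param_table")
  trees <- vector("list", length(plist) * n_reps)
  counter <- 0L
  for (i in seq_along(plist)) {
    for (r in seq_len(n_reps)) {
      counter <- counter + 1L
      trees[[counter]] <- simulate_tree(plist[[i]], branching, tt,
                                        seed = seed + counter, ...)
    }
  }
  g <- rep(ids, each = n_reps)
  summ <- data.frame(
    genotype_id = ids,
    nb_leaves = as.numeric(tapply(vapply(trees, `[[`, 0, "nb_leaves"), g, mean)[ids]),
    trunk_length = as.numeric(tapply(vapply(trees, `[[`, 0, "trunk_length"), g, mean)[ids]),
    nb_syll = as.numeric(tapply(vapply(trees, `[[`, 0, "nb_syll"), g, mean)[ids])
  )
  structure(list(trees = trees, summary = summ, n_reps = n_reps, seed = seed),
            class = "simulated_population")
}

.as_param_list <- function(param_table) {
  if (inherits(param_table, "genotype_params")) return(list(param_table))
  if (is.data.frame(param_table)) {
    need <- c("genotype_id", "rle_gdd", "in_length", "leaf_area", "a_syll")
    miss <- setdiff(need, names(param_table))
    if (length(miss)) stop("param_table missing column(s): ",
                           paste(miss, collapse = ", "))
    return(lapply(seq_len(nrow(param_table)), function(i) {
      genotype_params(param_table$rle_gdd[i], param_table$in_length[i],
                      param_table$leaf_area[i], param_table$a_syll[i],
                      param_table$genotype_id[i])
    }))
  }
  if (is.list(param_table)) return(param_table)
  stop("param_table must be a data frame or a list of genotype_params")
}

#' Frequency of sylleptic laterals along the trunk
#'
#' For each node rank, the fraction of trees possessing a node at that rank
#' that bear a sylleptic lateral there. Ranks reached by no tree get
#' frequency 0 with `n_trees = 0`.
#'
#' @param trees list of `simulated_tree` objects (or a
#'   `simulated_population`).
#' @param max_rank highest rank reported (>= 1).
#' @return data frame with columns `rank`, `freq`, `n_trees`.
#' @export
sylleptic_distribution <- function(trees, max_rank) {
  if (inherits(trees, "simulated_population")) trees <- trees$trees
  if (length(trees) == 0) stop("trees must be nonempty")
  if (max_rank < 1) stop("max_rank must be >= 1")
  n_at <- integer(max_rank)
  s_at <- integer(max_rank)
  for (tr in trees) {
    m <- tr$metamers
    top <- min(nrow(m), max_rank)
    if (top >= 1) {
      n_at[1:top] <- n_at[1:top] + 1L
      sy <- which(m$sylleptic[1:top])
      s_at[sy] <- s_at[sy] + 1L
    }
  }
  freq <- ifelse(n_at > 0, s_at / pmax(n_at, 1L), 0)
  data.frame(rank = seq_len(max_rank), freq = freq, n_trees = n_at)
}

#' Export a simulated tree as a metamer CSV
#'
#' One row per metamer, base to apex.
#'
#' @param tree a `simulated_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  utils::write.csv(tree$metamers, path, row.names = FALSE)
  invisible(path)
}

#' Export a simulated tree in minimal MTG text form
#'
#' Writes the topological code only: the trunk as a succession of metamers
#' (`^<`) following the scale header, with `+S` marking a sylleptic lateral
#' borne at a node. Geometric features are not exported.
#'
#' @param tree a `simulated_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mtg <- function(tree, path) {
  m <- tree$metamers
  lines <- c(
    "CODE:\tFORM-A",
    "CLASSES:",
    "SYMBOL\tSCALE\tDECOMPOSITION\tINDEXATION\tDEFINITION",
    "$\t0\tFREE\tFREE\tIMPLICIT",
    "T\t1\tFREE\tFREE\tEXPLICIT",
    "M\t2\tFREE\tFREE\tEXPLICIT",
    "S\t2\tFREE\tFREE\tEXPLICIT",
    "DESCRIPTION:",
    "LEFT\tRIGHT\tRELTYPE\tMAX",
    "M\tM\t<\t1",
    "M\tS\t+\t1",
    "FEATURES:",
    "NAME\tTYPE",
    "MTG:",
    "ENTITY-CODE",
    "/T1"
  )
  topo <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    code <- if (i == 1) paste0("^/M", m$rank[i]) else paste0("^<M", m$rank[i])
    if (m$sylleptic[i]) code <- paste0(code, "+S1")
    topo[i] <- paste0("\t", code)
  }
  writeLines(c(lines, topo), path)
  invisible(path)
}
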