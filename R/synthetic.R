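#' Configuration for the synthetic respondent generator
#'
#' The generator emulates the structure of a scored crowd-sourcing
#' cohort: by default 57 returned sheets covering 48 problems (5 criteria
#' each) and 45 solutions (2 criteria each).  Each (suggestion, criterion)
#' cell has a four-category response distribution controlled by a latent
#' merit `m`, an unsure weight `u` and an unaware rate `a`:
#'
#' \deqn{p_{unaware} = a,\quad p_{unsure} = (1-a)u,\quad
#'       p_{yes} = (1-a)(1-u)m,\quad p_{no} = (1-a)(1-u)(1-m)}
#'
#' Merits are drawn per suggestion from a Beta distribution and jittered
#' per criterion around the suggestion-level value.  With
#' `consensus_coupling = TRUE` (the default) high-merit suggestions get
#' proportionally lower unsure and unaware rates, reproducing the
#' field observation that top-ranked suggestions attract the strongest
#' consensus.
#'
#' @param n_scorers number of returned scoring sheets (default 57).
#' @param n_problems,n_solutions catalogue sizes (defaults 48 and 45).
#' @param unsure_weight baseline probability mass moved to `"unsure"`
#'   among non-blank answers (default 0.2).
#' @param unaware_rate baseline probability of a blank (unaware) cell
#'   (default 0.05; raw cohort rates are unpublished, so this is a
#'   modelling choice).
#' @param consensus_coupling couple unsure/unaware rates inversely to
#'   suggestion merit (default `TRUE`).
#' @param merit_shape1,merit_shape2 Beta parameters of the
#'   suggestion-level merit distribution (defaults 4.5 and 1.5, i.e. mean
#'   0.75, concentrating mass on suggestions a self-selected clinician
#'   panel would largely endorse).
#' @param merit_concentration Beta concentration of per-criterion merits
#'   around the suggestion-level merit (default 20).
#' @param scorer_bias_sd standard deviation of a per-scorer logit shift
#'   applied to cell merits; 0 (default) gives a homogeneous panel.
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_scorers = 57, n_problems = 48, n_solutions = 45,
                             unsure_weight = 0.2, unaware_rate = 0.05,
                             consensus_coupling = TRUE,
                             merit_shape1 = 4.5, merit_shape2 = 1.5,
                             merit_concentration = 20,
                             scorer_bias_sd = 0, seed = 1) {
  stopifnot(n_scorers >= 1, n_problems >= 0, n_solutions >= 0,
            n_problems + n_solutions >= 1,
            merit_shape1 > 0, merit_shape2 > 0, merit_concentration > 0,
            scorer_bias_sd >= 0, is.numeric(seed), length(seed) == 1)
  if (unsure_weight < 0 || unsure_weight > 1) {
    abort("`unsure_weight` must lie in [0, 1]")
  }
  if (unaware_rate < 0 || unaware_rate >= 1) {
    abort("`unaware_rate` must lie in [0, 1)")
  }
  structure(
    list(
      n_scorers = as.integer(n_scorers),
      n_problems = as.integer(n_problems),
      n_solutions = as.integer(n_solutions),
      unsure_weight = unsure_weight, unaware_rate = unaware_rate,
      consensus_coupling = isTRUE(consensus_coupling),
      merit_shape1 = merit_shape1, merit_shape2 = merit_shape2,
      merit_concentration = merit_concentration,
      scorer_bias_sd = scorer_bias_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d scorers, %d problems, %d solutions (seed %d)\n",
    x$n_scorers, x$n_problems, x$n_solutions, x$seed
  ))
  cat(sprintf(
    "  unsure_weight %.3g, unaware_rate %.3g, consensus_coupling %s, merit Beta(%.3g, %.3g)\n",
    x$unsure_weight, x$unaware_rate, x$consensus_coupling,
    x$merit_shape1, x$merit_shape2
  ))
  invisible(x)
}

#' Cell response distribution from generative parameters
#'
#' @param merit merit `m` in \[0, 1\] (vectorised).
#' @param unsure_weight unsure weight `u` in \[0, 1\].
#' @param unaware_rate unaware rate `a` in \[0, 1).
#' @return data frame with columns `p_yes`, `p_no`, `p_unsure`,
#'   `p_unaware`; each row a valid probability distribution.
#' @export
cell_distribution <- function(merit, unsure_weight, unaware_rate) {
  n <- max(length(merit), length(unsure_weight), length(unaware_rate))
  m <- rep_len(merit, n); u <- rep_len(unsure_weight, n)
  a <- rep_len(unaware_rate, n)
  if (any(m < 0 | m > 1)) abort("`merit` must lie in [0, 1]")
  if (any(u < 0 | u > 1)) abort("`unsure_weight` must lie in [0, 1]")
  if (any(a < 0 | a >= 1)) abort("`unaware_rate` must lie in [0, 1)")
  data.frame(
    p_yes = (1 - a) * (1 - u) * m,
    p_no = (1 - a) * (1 - u) * (1 - m),
    p_unsure = (1 - a) * u,
    p_unaware = a
  )
}

check_distribution <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 4) abort("a cell distribution has four probabilities")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8)) {
    abort("invalid cell distribution: probabilities must be >= 0 and sum to 1")
  }
  p
}

#' Analytic expected intermediate score of a cell distribution
#'
#' Expectation (as the number of scorers grows) of the intermediate score
#' produced by sampling responses from the given distribution:
#' `100 * (p_yes + 0.5 p_unsure) / (p_yes + p_no + p_unsure)`.  Undefined
#' (`NA`) when all mass is on unaware.
#'
#' @param p_yes,p_no,p_unsure,p_unaware cell probabilities (vectorised).
#' @return expected score on the 0-100 scale.
#' @examples
#' expected_intermediate_score(0.3, 0.1, 0.2, 0.4)  # 66.67
#' @export
expected_intermediate_score <- function(p_yes, p_no, p_unsure, p_unaware) {
  check_distribution(cbind(p_yes, p_no, p_unsure, p_unaware))
  received <- p_yes + p_no + p_unsure
  ifelse(received > 0, 100 * (p_yes + 0.5 * p_unsure) / received, NA_real_)
}

# All ways to split n scorers across the four response categories.
compositions4 <- function(n) {
  g <- expand.grid(k1 = 0:n, k2 = 0:n, k3 = 0:n, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$k1 + g$k2 + g$k3 <= n, ]
  g$k4 <- n - g$k1 - g$k2 - g$k3
  as.matrix(g)
}

# Exact first two moments of the modal fraction for counts ~
# Multinomial(n, p).
mode_fraction_moments_exact <- function(p, n) {
  ks <- compositions4(n)
  lp <- lgamma(n + 1) - rowSums(lgamma(ks + 1)) +
    as.vector(ks %*% ifelse(p > 0, log(p), 0))
  lp[rowSums(ks[, p == 0, drop = FALSE]) > 0] <- -Inf
  prob <- exp(lp)
  f <- apply(ks, 1, max) / n
  m1 <- sum(prob * f)
  list(mean = m1, var = sum(prob * f^2) - m1^2)
}

#' Expected AEA under a synthetic cell model
#'
#' Expectation of the AEA statistic for one suggestion whose criteria have
#' the given response distributions, at a panel size of `n_scorers`.  For
#' small panels the expectation is exact, by enumerating every multinomial
#' split of the scorers over the four response categories; for larger
#' panels it is estimated by Monte Carlo with a reported standard error.
#'
#' @param probs cell distribution(s): a vector of four probabilities
#'   (yes, no, unsure, unaware) or a matrix/data frame with one such row
#'   per criterion.
#' @param n_scorers panel size.
#' @param method `"exact"`, `"mc"`, or `"auto"` (exact up to 25 scorers,
#'   where the composition count is still tiny, Monte Carlo above).
#' @param n_sim Monte Carlo replicates (method `"mc"`).
#' @return list with `value` (expected AEA), `sd` (standard deviation of
#'   a single cohort's AEA at this panel size), `se` (Monte Carlo standard
#'   error of `value`; 0 for exact), and `per_criterion` (data frame of
#'   per-criterion means and variances of the modal fraction).
#' @examples
#' expected_aea(rep(0.25, 4), n_scorers = 2)  # 0.625
#' @export
expected_aea <- function(probs, n_scorers, method = c("auto", "exact", "mc"),
                         n_sim = 2000) {
  method <- match.arg(method)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  p <- check_distribution(probs)
  stopifnot(n_scorers >= 1)
  if (method == "auto") method <- if (n_scorers <= 25) "exact" else "mc"
  k <- nrow(p)

  if (method == "exact") {
    mom <- lapply(seq_len(k), function(i) {
      mode_fraction_moments_exact(p[i, ], n_scorers)
    })
    means <- vapply(mom, `[[`, numeric(1), "mean")
    vars <- vapply(mom, `[[`, numeric(1), "var")
    list(
      value = mean(means),
      sd = sqrt(sum(vars)) / k,
      se = 0,
      per_criterion = data.frame(criterion = seq_len(k), mean = means,
                                 var = vars)
    )
  } else {
    sims <- matrix(0, nrow = k, ncol = n_sim)
    for (i in seq_len(k)) {
      counts <- stats::rmultinom(n_sim, n_scorers, p[i, ])
      sims[i, ] <- pmax(counts[1, ], counts[2, ], counts[3, ], counts[4, ]) /
        n_scorers
    }
    aea_sims <- colMeans(sims)
    list(
      value = mean(aea_sims),
      sd = stats::sd(aea_sims),
      se = stats::sd(aea_sims) / sqrt(n_sim),
      per_criterion = data.frame(
        criterion = seq_len(k),
        mean = rowMeans(sims),
        var = apply(sims, 1, stats::var)
      )
    )
  }
}

draw_suggestion_params <- function(n, prefix, config) {
  mu <- stats::rbeta(n, config$merit_shape1, config$merit_shape2)
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  if (config$consensus_coupling) {
    u <- pmin(2 * config$unsure_weight * (1 - mu), 0.95)
    a <- pmin(2 * config$unaware_rate * (1 - mu), 0.5)
  } else {
    u <- rep(config$unsure_weight, n)
    a <- rep(config$unaware_rate, n)
  }
  data.frame(
    suggestion_id = sprintf("%s%03d", prefix, seq_len(n)),
    merit = mu, unsure_weight = u, unaware_rate = a,
    stringsAsFactors = FALSE
  )
}

generate_kind <- function(kind, params, criterion_set, scorers, config) {
  kappa <- config$merit_concentration
  crit_ids <- criterion_set$criteria$id
  k <- length(crit_ids)
  n_sugg <- nrow(params)
  n_cells <- n_sugg * k

  cell <- data.frame(
    kind = kind,
    suggestion_id = rep(params$suggestion_id, each = k),
    criterion_id = rep(crit_ids, times = n_sugg),
    merit_suggestion = rep(params$merit, each = k),
    stringsAsFactors = FALSE
  )
  mu <- rep(params$merit, each = k)
  m <- stats::rbeta(n_cells, kappa * mu, kappa * (1 - mu))
  u <- rep(params$unsure_weight, each = k)
  a <- rep(params$unaware_rate, each = k)
  dist <- cell_distribution(m, u, a)
  truth <- cbind(cell, merit = m, unsure_weight = u, unaware_rate = a, dist)
  truth$expected_score <- expected_intermediate_score(
    dist$p_yes, dist$p_no, dist$p_unsure, dist$p_unaware
  )

  n_sc <- length(scorers)
  if (config$scorer_bias_sd > 0) {
    bias <- stats::rnorm(n_sc, 0, config$scorer_bias_sd)
    m_cs <- stats::plogis(outer(stats::qlogis(pmin(pmax(m, 1e-8), 1 - 1e-8)),
                                bias, `+`))
    p_yes <- (1 - a) * (1 - u) * m_cs
    p_no <- (1 - a) * (1 - u) * (1 - m_cs)
    p_unsure <- matrix((1 - a) * u, n_cells, n_sc)
  } else {
    p_yes <- matrix(dist$p_yes, n_cells, n_sc)
    p_no <- matrix(dist$p_no, n_cells, n_sc)
    p_unsure <- matrix(dist$p_unsure, n_cells, n_sc)
  }
  r <- matrix(stats::runif(n_cells * n_sc), n_cells, n_sc)
  idx <- 1L + (r > p_yes) + (r > p_yes + p_no) + (r > p_yes + p_no + p_unsure)
  codes <- response_codes()[c(1L, 2L, 3L, 4L)]

  cells <- data.frame(
    scorer_id = rep(scorers, each = n_cells),
    suggestion_id = rep(cell$suggestion_id, times = n_sc),
    criterion_id = rep(cell$criterion_id, times = n_sc),
    response = codes[as.vector(idx)],
    stringsAsFactors = FALSE
  )
  list(
    matrix = response_matrix(cells, kind, scorers = scorers,
                             suggestions = params$suggestion_id,
                             criteria = crit_ids),
    truth = truth
  )
}

#' Generate a synthetic scored cohort
#'
#' Draws suggestion merits, builds per-cell response distributions, and
#' samples a complete scorer x suggestion x criterion response grid for
#' problems and solutions.  The returned ground-truth table records every
#' cell's distribution and analytic expected intermediate score, so
#' recovery of known parameters by the scoring pipeline can be tested.
#'
#' @param config a [synthetic_config()].
#' @param problem_criteria,solution_criteria criterion sets to score
#'   against; defaults to [default_criteria()].
#' @return list of class `synthetic_cohort` with elements `problems` and
#'   `solutions` (response matrices), `catalogue` (suggestion catalogue
#'   data frame), `truth` (per-cell ground truth) and `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_scorers = 10, n_problems = 4,
#'                                            n_solutions = 3, seed = 7))
#' rank_table(cohort$problems, default_criteria("problem"))
#' @export
generate_cohort <- function(config = synthetic_config(),
                            problem_criteria = default_criteria("problem"),
                            solution_criteria = default_criteria("solution")) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  scorers <- sprintf("scorer_%03d", seq_len(config$n_scorers))

  p_params <- draw_suggestion_params(config$n_problems, "P", config)
  s_params <- draw_suggestion_params(config$n_solutions, "S", config)

  catalogue <- data.frame(
    id = c(p_params$suggestion_id, s_params$suggestion_id),
    text = c(sprintf("Synthetic problem statement %d", seq_len(config$n_problems)),
             sprintf("Synthetic solution statement %d", seq_len(config$n_solutions))),
    kind = c(rep("problem", config$n_problems),
             rep("solution", config$n_solutions)),
    breakdown_point = sample(breakdown_points(),
                             config$n_problems + config$n_solutions,
                             replace = TRUE),
    factor = sample(factor_categories(),
                    config$n_problems + config$n_solutions, replace = TRUE),
    stringsAsFactors = FALSE
  )

  problems <- generate_kind("problem", p_params, problem_criteria, scorers,
                            config)
  solutions <- generate_kind("solution", s_params, solution_criteria, scorers,
                             config)

  structure(
    list(
      problems = problems$matrix,
      solutions = solutions$matrix,
      catalogue = catalogue,
      truth = rbind(problems$truth, solutions$truth),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d scorers | %d problems, %d solutions (seed %d)\n",
    x$config$n_scorers, x$config$n_problems, x$config$n_solutions,
    x$config$seed
  ))
  invisible(x)
}
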