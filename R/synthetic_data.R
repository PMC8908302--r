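# Generative counterpart of the latent-superposition model: plant K latent
# subnetworks (memberships, tie weights U_true, activity schedules H_true),
# observe nonnegative per-epoch dyadic counts, and optionally emit a raw
# detection log and a survey with known effect structure. Everything is
# seeded and round-trips through the same file formats as the real-data
# path.

#' Default synthetic scenario
#'
#' A community of 30 participants in 3 disjoint latent subnetworks of 10
#' over six weeks of 30-minute epochs (I = 2016), mirroring the qualitative
#' temporal signatures seen in farming-community proximity data: an
#' event-spike layer (collective work days), a diurnal family layer
#' (morning/evening contacts every day), and a weekday-daytime hub layer
#' with a midday dip. Tie weights are i.i.d. Uniform(0.5, 1.5) on each
#' factor's internal dyads; counts are capped at 12 (both directions times
#' one detection per 5-minute scan in a 30-minute epoch).
#'
#' @return A scenario list understood by [generate_truth()].
#' @export
default_scenario <- function() {
  list(
    N = 30L,
    K = 3L,
    start = "2018-01-01", end = "2018-02-11", epoch_minutes = 30L,
    membership_sizes = c(10L, 10L, 10L),
    disjoint = TRUE,
    weight_min = 0.5, weight_max = 1.5,
    cap = 12L,
    layers = list(
      list(type = "event",
           days = c(6L, 10L, 14L, 20L, 24L, 28L, 34L, 38L),
           start_hour = 8, end_hour = 17, amplitude = 5),
      list(type = "diurnal",
           windows = list(c(6, 8), c(18, 22)), amplitude = 1.2),
      list(type = "hub",
           start_hour = 9, end_hour = 17,
           dip = c(12, 13), dip_factor = 0.5, amplitude = 1)
    )
  )
}

layer_schedule <- function(layer, grid) {
  starts <- epoch_start_times(grid)
  hour <- as.numeric(format(starts, "%H")) +
    as.numeric(format(starts, "%M")) / 60
  day <- as.integer(as.Date(starts, tz = grid$timezone) -
                      grid$start_date) + 1L
  wday <- as.POSIXlt(starts)$wday  # 0 = Sunday
  h <- numeric(grid$I)
  amp <- layer$amplitude
  if (layer$type == "event") {
    on <- day %in% layer$days & hour >= layer$start_hour &
      hour < layer$end_hour
    h[on] <- amp
  } else if (layer$type == "diurnal") {
    for (w in layer$windows) {
      h[hour >= w[1] & hour < w[2]] <- amp
    }
  } else if (layer$type == "hub") {
    on <- wday %in% 1:5 & hour >= layer$start_hour & hour < layer$end_hour
    h[on] <- amp
    dipped <- on & hour >= layer$dip[1] & hour < layer$dip[2]
    h[dipped] <- amp * layer$dip_factor
  } else {
    stop("unknown layer type: ", layer$type, call. = FALSE)
  }
  h
}

#' Generate a planted synthetic truth
#'
#' Draws factor memberships and tie weights and builds activity schedules
#' from the scenario's layer templates. Row `k` of `U_true` is positive
#' only on dyads internal to factor `k`'s membership; `H_true` columns are
#' the layer schedules. Deterministic given `seed`.
#'
#' @param scenario Scenario list, see [default_scenario()].
#' @param seed RNG seed.
#' @return A `synthetic_truth` list: `N`, `K_true`, `participants`, `grid`,
#'   `dyads`, `memberships` (list of id vectors), `U_true` (K x J),
#'   `H_true` (I x K), `cap`, `seed`.
#' @export
generate_truth <- function(scenario = default_scenario(), seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  N <- scenario$N
  K <- scenario$K
  sizes <- scenario$membership_sizes
  if (length(sizes) != K) stop("need one membership size per factor",
                               call. = FALSE)
  if (any(sizes > N)) stop("membership larger than N", call. = FALSE)
  ids <- sprintf("p%02d", seq_len(N))
  grid <- build_epoch_grid(scenario$start, scenario$end,
                           scenario$epoch_minutes)
  dyads <- build_dyad_index(ids)

  memberships <- vector("list", K)
  if (isTRUE(scenario$disjoint)) {
    if (sum(sizes) > N) stop("disjoint memberships exceed N", call. = FALSE)
    pool <- sample(ids)
    off <- 0L
    for (k in seq_len(K)) {
      memberships[[k]] <- sort(pool[(off + 1L):(off + sizes[k])])
      off <- off + sizes[k]
    }
  } else {
    for (k in seq_len(K)) {
      memberships[[k]] <- sort(sample(ids, sizes[k]))
    }
  }

  U_true <- matrix(0, K, dyads$J)
  for (k in seq_len(K)) {
    internal <- dyads$pairs[, 1L] %in% memberships[[k]] &
      dyads$pairs[, 2L] %in% memberships[[k]]
    U_true[k, internal] <- stats::runif(sum(internal),
                                        scenario$weight_min,
                                        scenario$weight_max)
  }
  H_true <- vapply(scenario$layers[seq_len(K)], layer_schedule,
                   numeric(grid$I), grid = grid)

  structure(list(N = N, K_true = K, participants = ids, grid = grid,
                 dyads = dyads, memberships = memberships,
                 U_true = U_true, H_true = H_true,
                 cap = scenario$cap, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Observe a contact matrix from a planted truth
#'
#' Superposes the planted layers into per-cell rates `(H_true U_true)[i, j]`
#' and observes counts either as `Poisson(rate)` draws or as the rounded
#' rate, truncated at `cap`.
#'
#' @param truth A `synthetic_truth`.
#' @param noise_model `"poisson"` (default) or `"rounded"` (deterministic).
#' @param cap Count cap; defaults to the truth's cap.
#' @param seed RNG seed (poisson model only).
#' @return A `contact_matrix`.
#' @export
observe_contacts <- function(truth, noise_model = c("poisson", "rounded"),
                             cap = truth$cap, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!is.null(cap) && cap < 0) stop("cap must be nonnegative", call. = FALSE)
  rate <- truth$H_true %*% truth$U_true
  if (noise_model == "poisson") {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    Yd <- matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  } else {
    Yd <- round(rate)
  }
  if (!is.null(cap)) Yd <- pmin(Yd, cap)
  new_contact_matrix(Matrix::Matrix(Yd, sparse = TRUE), truth$grid,
                     truth$dyads)
}

#' Emit a raw detection log realizing a contact matrix
#'
#' Writes `y[i, j]` detection records for dyad `j`, spread uniformly at
#' random inside epoch `i`, with directions alternating between the two
#' members. Rebuilding the matrix from the emitted log under
#' `direction_rule = "sum"` reproduces `Y` exactly.
#'
#' @param cm A `contact_matrix`.
#' @param seed RNG seed for the within-epoch times.
#' @return A `detection_log`, ordered by timestamp.
#' @export
emit_detection_log <- function(cm, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  trip <- Matrix::summary(cm$Y)
  n_tot <- sum(trip$x)
  if (n_tot == 0) {
    return(new_detection_log(
      as.POSIXct(character(), tz = cm$grid$timezone), character(),
      character()))
  }
  counts <- as.integer(trip$x)
  epoch_i <- rep(trip$i, counts)
  dyad_j <- rep(trip$j, counts)
  # alternate direction within each cell: 1st record a->b, 2nd b->a, ...
  within <- sequence(counts)
  a <- cm$dyads$pairs[dyad_j, 1L]
  b <- cm$dyads$pairs[dyad_j, 2L]
  obs <- ifelse(within %% 2L == 1L, a, b)
  seen <- ifelse(within %% 2L == 1L, b, a)
  epoch0 <- epoch_start_times(cm$grid)[epoch_i]
  offset <- stats::runif(length(epoch_i), 0, cm$grid$epoch_minutes * 60)
  ts <- epoch0 + floor(offset)  # whole seconds keep the text format lossless
  ord <- order(ts, obs, seen)
  new_detection_log(ts[ord], obs[ord], seen[ord])
}

# Maximum-total-score assignment of model factors to truth factors.
# Exhaustive over permutations for K <= 8 (exact Hungarian answer at these
# sizes), greedy above.
match_factors <- function(score) {
  K <- nrow(score)
  s <- score
  s[is.na(s)] <- 0
  if (K <= 8L) {
    perms <- permutations_of(K)
    tot <- vapply(perms, function(p) sum(s[cbind(seq_len(K), p)]),
                  numeric(1L))
    perms[[which.max(tot)]]
  } else {
    p <- integer(K)
    avail <- seq_len(K)
    for (k in order(-apply(s, 1L, max))) {
      pick <- avail[which.max(s[k, avail])]
      p[k] <- pick
      avail <- setdiff(avail, pick)
    }
    p
  }
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Score recovery of a planted truth by a fitted model
#'
#' Matches fitted factors to planted factors by the permutation maximizing
#' total Pearson correlation between `U` rows, then reports per-factor
#' matched correlations for `U` rows and `H` columns, and membership
#' precision/recall at a weight threshold (a participant belongs to an
#' estimated factor when some incident dyad weight exceeds
#' `threshold_frac` times the factor's maximum weight).
#'
#' @param truth A `synthetic_truth`.
#' @param model A `factor_model` with `model$K == truth$K_true`.
#' @param threshold_frac Membership weight threshold as a fraction of each
#'   row's maximum.
#' @return List: `assignment` (truth factor -> model factor), `u_cor`,
#'   `h_cor` (per truth factor; `NA` when a factor is constant),
#'   `mean_u_cor`, `membership` (data.frame `factor`, `precision`,
#'   `recall`).
#' @export
evaluate_recovery <- function(truth, model, threshold_frac = 0.1) {
  K <- truth$K_true
  if (model$K != K) stop("model rank differs from planted rank", call. = FALSE)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  cu <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      cu[a, b] <- safe_cor(truth$U_true[a, ], model$U[b, ])
    }
  }
  perm <- match_factors(cu)
  u_cor <- cu[cbind(seq_len(K), perm)]
  h_cor <- vapply(seq_len(K), function(k) {
    safe_cor(truth$H_true[, k], model$H[, perm[k]])
  }, numeric(1L))

  member_of <- function(U_row) {
    thr <- threshold_frac * max(U_row)
    keep <- U_row > thr
    sort(unique(c(truth$dyads$pairs[keep, 1L],
                  truth$dyads$pairs[keep, 2L])))
  }
  memb <- do.call(rbind, lapply(seq_len(K), function(k) {
    est <- member_of(model$U[perm[k], ])
    tru <- truth$memberships[[k]]
    tp <- length(intersect(est, tru))
    data.frame(factor = k,
               precision = if (length(est)) tp / length(est) else NA_real_,
               recall = if (length(tru)) tp / length(tru) else NA_real_)
  }))
  list(assignment = perm, u_cor = u_cor, h_cor = h_cor,
       mean_u_cor = mean(u_cor, na.rm = TRUE), membership = memb)
}

#' Generate a synthetic survey with planted effects
#'
#' Builds per-participant planted trait scores (log eigenvector centrality
#' in each planted subnetwork, standardized) and generates item responses
#' as a rounded, range-clipped linear function of the mapped trait plus
#' Gaussian noise, so that scale-centrality correlations have known sign
#' and approximate size.
#'
#' @param truth A `synthetic_truth`.
#' @param effect_map data.frame with columns `scale`, `factor`, `slope`:
#'   which planted factor drives each scale and how strongly (response-scale
#'   points per standard deviation of trait). Scales absent from the map get
#'   slope 0. Default: pro-community attitude driven by factor 1, subjective
#'   health by factor 3.
#' @param seed RNG seed.
#' @param noise_sd Item-level Gaussian noise standard deviation.
#' @param codebook Codebook data.frame, see [load_codebook()].
#' @return Survey data.frame (`participant_id` plus one column per codebook
#'   item) with attribute `planted_traits` (participant x factor matrix of
#'   standardized log centralities).
#' @export
generate_survey <- function(truth,
                            effect_map = data.frame(
                              scale = c("pro_community", "subjective_health"),
                              factor = c(1L, 3L),
                              slope = c(0.8, 0.6)),
                            seed = 1L, noise_sd = 0.8,
                            codebook = load_codebook()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  K <- truth$K_true
  traits <- matrix(0, truth$N, K,
                   dimnames = list(truth$participants, NULL))
  for (k in seq_len(K)) {
    g <- structure(list(factor_index = k, nodes = truth$participants,
                        edges = data.frame(
                          a = truth$dyads$pairs[truth$U_true[k, ] > 0, 1L],
                          b = truth$dyads$pairs[truth$U_true[k, ] > 0, 2L],
                          weight = truth$U_true[k, truth$U_true[k, ] > 0]),
                        weight_threshold = 0),
                   class = "subnetwork_graph")
    lc <- log_centrality(eigenvector_centrality(g))
    traits[, k] <- as.numeric(scale(lc))
  }

  out <- data.frame(participant_id = truth$participants)
  for (r in seq_len(nrow(codebook))) {
    it <- codebook[r, ]
    hit <- effect_map[effect_map$scale == it$scale, , drop = FALSE]
    slope <- if (nrow(hit)) hit$slope[1L] else 0
    trait <- if (nrow(hit) && hit$factor[1L] <= K) traits[, hit$factor[1L]]
             else 0
    mid <- (it$min + it$max) / 2
    resp <- round(mid + slope * trait +
                    stats::rnorm(truth$N, sd = noise_sd))
    out[[it$item]] <- pmin(pmax(resp, it$min), it$max)
  }
  attr(out, "planted_traits") <- traits
  out
}
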