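# Synthetic mixed-array pollination experiments with known ground truth.
#
# The generator emulates a 6x6 array of 24 parental plants plus 12 F2 hybrids,
# pollinator trip bouts whose visit choices follow a linear+quadratic
# log-preference on standardized floral traits, geometric pollen carryover,
# and single-pollen genotyping noise (allelic dropout, typing error,
# multi-grain contamination).

#' Simulation configuration
#'
#' @param n_parental,n_f2 array composition (24 + 12 by default, a 6x6 grid).
#' @param grid array dimensions (rows, cols); must hold all plants.
#' @param panel marker panel (\code{\link{default_panel}} by default); each
#'   locus' allele codes are split into two disjoint parental pools.
#' @param trait_model per-trait list with parental \code{mean}/\code{sd},
#'   F2 \code{mean}/\code{sd} and F2 truncation \code{range}.
#' @param preference per-pollinator linear (\code{b}) and quadratic (\code{g})
#'   attraction coefficients on the log-rate scale, applied to standardized
#'   traits; drives the softmax visit choice.
#' @param bout_model list: \code{mean_visits} (Poisson mean of bout length,
#'   minimum 1) and \code{max_visits_per_flower} (2: flowers receive 0--2
#'   visits per bout).
#' @param transport list: \code{grains_per_pickup} P, per-visit deposition
#'   fraction \code{d} in (0, 1], self-deposit fraction \code{s}.
#' @param noise list: per-locus \code{dropout}, per-grain
#'   \code{contamination}, per-allele typing \code{error} rates.
#' @param pollinator \code{"butterfly"} or \code{"hawkmoth"}; selects the
#'   preference vector, bout length and noise preset (hawkmoth samples amplify
#'   less well, hence a higher dropout preset).
#' @param n_bouts number of trip bouts to simulate (8 butterfly / 11 hawkmoth
#'   presets).
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(n_parental = 24L, n_f2 = 12L, grid = c(6L, 6L),
                              panel = default_panel(),
                              trait_model = NULL, preference = NULL,
                              bout_model = NULL, transport = NULL,
                              noise = NULL,
                              pollinator = c("butterfly", "hawkmoth"),
                              n_bouts = NULL) {
  pollinator <- match.arg(pollinator)
  if (n_parental + n_f2 > prod(grid)) stop("grid too small for the plants")
  if (n_parental <= 0L || n_f2 <= 0L) stop("plant counts must be positive")
  if (is.null(trait_model)) trait_model <- default_trait_model()
  if (is.null(preference)) preference <- default_preference()[[pollinator]]
  if (is.null(bout_model))
    bout_model <- list(mean_visits = 9, max_visits_per_flower = 2L)
  if (is.null(transport))
    transport <- list(grains_per_pickup = 30L, d = 0.07, s = 0.5)
  if (is.null(noise))
    noise <- list(dropout = if (pollinator == "hawkmoth") 0.25 else 0.10,
                  contamination = 0.05, error = 0.01)
  if (is.null(n_bouts)) n_bouts <- if (pollinator == "hawkmoth") 11L else 8L
  stopifnot(transport$d > 0, transport$d <= 1,
            transport$s >= 0, transport$s <= 1,
            noise$dropout >= 0, noise$dropout <= 1,
            noise$contamination >= 0, noise$contamination <= 1,
            noise$error >= 0, noise$error <= 1)
  for (tm in trait_model)
    if (tm$range[1] > tm$range[2])
      stop("config error: impossible truncation range (min > max)")
  structure(list(n_parental = as.integer(n_parental), n_f2 = as.integer(n_f2),
                 grid = as.integer(grid), panel = panel,
                 trait_model = trait_model, preference = preference,
                 bout_model = bout_model, transport = transport, noise = noise,
                 pollinator = pollinator, n_bouts = as.integer(n_bouts)),
            class = "sim_config")
}

trait_names <- function() c("tepal_color", "scent_intensity",
                            "corolla_direction", "stem_height", "asd")

# Parental distributions are tight around the butterfly-syndrome phenotype;
# F2 distributions are wide (trait segregation), truncated to realistic ranges
# (tepal colour segregates across the full 3-23 colour-chart span).
default_trait_model <- function() {
  list(
    tepal_color       = list(p_mean = 22.8, p_sd = 0.3, f2_mean = 11.9,
                             f2_sd = 5.0, range = c(3, 23)),
    scent_intensity   = list(p_mean = 3,    p_sd = 1.0, f2_mean = 25,
                             f2_sd = 20,  range = c(0, 80)),
    corolla_direction = list(p_mean = 56.1, p_sd = 4.0, f2_mean = 48,
                             f2_sd = 8,   range = c(20, 80)),
    stem_height       = list(p_mean = 100,  p_sd = 8.0, f2_mean = 90,
                             f2_sd = 15,  range = c(50, 130)),
    asd               = list(p_mean = 4.0,  p_sd = 0.5, f2_mean = 2.5,
                             f2_sd = 1.2, range = c(0.2, 6))
  )
}

# Attraction coefficients on standardized traits (log-rate scale).
# Butterflies: stabilizing preference on weak scent, mild preference for
# redder, taller plants. Hawkmoths: directional preference on tepal colour.
default_preference <- function() {
  zero <- stats::setNames(numeric(5), trait_names())
  b_b <- zero; b_b[c("tepal_color", "scent_intensity", "stem_height")] <-
    c(0.3, -0.3, 0.3)
  g_b <- zero; g_b[c("scent_intensity", "stem_height")] <- c(-0.8, -0.2)
  b_h <- zero; b_h["tepal_color"] <- 0.5
  list(butterfly = list(b = b_b, g = g_b),
       hawkmoth  = list(b = b_h, g = zero))
}

rnorm_trunc <- function(n, mean, sd, range) {
  out <- numeric(n); need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= range[1] & x <= range[2]
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate array plants with segregating floral traits
#'
#' Parental plants draw traits from tight parental distributions; F2 hybrids
#' draw from wide segregation distributions truncated to the configured
#' ranges.
#'
#' @param config a \code{sim_config}.
#' @param seed integer seed (deterministic output).
#' @return data.frame: genet_id, class, and the five floral traits.
#' @export
generate_plants <- function(config, seed = 1L) {
  set.seed(seed)
  n_p <- config$n_parental; n_f <- config$n_f2
  genet <- c(sprintf("P%02d", seq_len(n_p)), sprintf("F%02d", seq_len(n_f)))
  klass <- rep(c("parental_fulva", "f2_hybrid"), c(n_p, n_f))
  df <- data.frame(genet_id = genet, class = klass,
                   stringsAsFactors = FALSE)
  for (tr in trait_names()) {
    tm <- config$trait_model[[tr]]
    df[[tr]] <- c(rnorm_trunc(n_p, tm$p_mean, tm$p_sd, tm$range),
                  rnorm_trunc(n_f, tm$f2_mean, tm$f2_sd, tm$range))
  }
  df
}

#' Generate multilocus genotypes by simulated crossing
#'
#' Parental plants draw both alleles from their species pool (first half of
#' each locus' panel alleles). F2 hybrids are produced through an F1 pair:
#' each F1 carries one allele from each species pool per locus, and each F2
#' locus is an independent draw of one gamete from each F1.
#'
#' @param config a \code{sim_config}.
#' @param plants data.frame from \code{\link{generate_plants}}.
#' @param seed integer seed.
#' @return genotype data.frame: genet_id, locus, allele1, allele2.
#' @export
generate_genotypes <- function(config, plants, seed = 1L) {
  set.seed(seed)
  pools <- panel_pools(config$panel)
  for (loc in names(pools))
    if (length(pools[[loc]]$A) < 2L || length(pools[[loc]]$B) < 2L)
      stop("config error: locus ", loc, " has < 2 alleles in a parental pool")
  rows <- list(); f1_pairs <- list()
  is_f2 <- plants$class == "f2_hybrid"
  for (loc in names(pools)) {
    A <- pools[[loc]]$A; B <- pools[[loc]]$B
    n_p <- sum(!is_f2); n_f <- sum(is_f2)
    pa1 <- sample(A, n_p, replace = TRUE)
    pa2 <- sample(A, n_p, replace = TRUE)
    # one F1 pair: each F1 is (species-A allele / species-B allele)
    f1 <- list(c(sample(A, 1L), sample(B, 1L)),
               c(sample(A, 1L), sample(B, 1L)))
    f1_pairs[[loc]] <- f1
    fa1 <- sample(f1[[1]], n_f, replace = TRUE)
    fa2 <- sample(f1[[2]], n_f, replace = TRUE)
    a1 <- integer(nrow(plants)); a2 <- integer(nrow(plants))
    a1[!is_f2] <- pa1; a2[!is_f2] <- pa2
    a1[is_f2] <- fa1;  a2[is_f2] <- fa2
    rows[[loc]] <- data.frame(genet_id = plants$genet_id, locus = loc,
                              allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$genet_id, out$locus), , drop = FALSE]
  attr(out, "f1_pair") <- f1_pairs
  out
}

# Softmax visit probabilities from the linear+quadratic log-preference on
# standardized traits.
visit_probs <- function(z, pref) {
  eta <- as.numeric(z %*% pref$b + (z^2) %*% pref$g)
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' Simulate one pollinator trip bout with pollen transport
#'
#' Visit choices follow a softmax over per-flower log-preference
#' \eqn{\sum_k b_k x_k + g_k x_k^2} on standardized traits, with at most
#' \code{max_visits_per_flower} visits per flower per bout. The pollinator
#' carries pollen cohorts: at each visit it first deposits a binomial fraction
#' \code{d} of every carried cohort and a fraction \code{s} of the current
#' flower's own pollen (self deposition), then picks up \code{grains_per_pickup}
#' grains from the current flower's anthers. Grains can only land on flowers
#' visited after their pickup, so a length-1 bout yields no outcross
#' deposition.
#'
#' @param flowers data.frame of the flowers open during this bout: flower_id,
#'   genet_id and the five trait columns.
#' @param config a \code{sim_config}.
#' @param bout_id identifier for the bout.
#' @param seed integer seed.
#' @return list with \code{visits} (data.frame bout_id, pollinator,
#'   visit_order, flower_id) and \code{events} (data.frame grain_id,
#'   true_donor_id, stigma_flower_id, bout_id, visit_index).
#' @export
simulate_bout <- function(flowers, config, bout_id = "B1", seed = 1L) {
  set.seed(seed)
  stopifnot(nrow(flowers) >= 1L)
  z <- scale(as.matrix(flowers[, trait_names()]))
  z[is.nan(z)] <- 0   # zero-variance trait in a degenerate array
  n_visits <- max(1L, stats::rpois(1L, config$bout_model$mean_visits))
  cap <- config$bout_model$max_visits_per_flower
  tr <- config$transport
  visits <- integer(0)
  count <- integer(nrow(flowers))
  cohorts <- list()  # each: list(donor, flower, remaining)
  events <- vector("list", n_visits)
  grain_counter <- 0L
  for (v in seq_len(n_visits)) {
    open <- which(count < cap)
    if (!length(open)) break
    p <- visit_probs(z[open, , drop = FALSE], config$preference)
    i <- open[sample.int(length(open), 1L, prob = p)]
    count[i] <- count[i] + 1L
    visits <- c(visits, i)
    # deposit carried cohorts, then self pollen, then pick up
    dep <- list()
    for (ci in seq_along(cohorts)) {
      co <- cohorts[[ci]]
      if (co$remaining <= 0L) next
      k <- stats::rbinom(1L, co$remaining, tr$d)
      cohorts[[ci]]$remaining <- co$remaining - k
      if (k > 0L) dep[[length(dep) + 1L]] <- c(donor = co$donor, n = k)
    }
    k_self <- stats::rbinom(1L, tr$grains_per_pickup, tr$s)
    if (k_self > 0L)
      dep[[length(dep) + 1L]] <- c(donor = flowers$genet_id[i], n = k_self)
    if (length(dep)) {
      donors <- unlist(lapply(dep, function(x) rep(x[["donor"]],
                                                   as.integer(x[["n"]]))))
      ids <- sprintf("%s_g%04d", bout_id, grain_counter + seq_along(donors))
      grain_counter <- grain_counter + length(donors)
      events[[v]] <- data.frame(grain_id = ids, true_donor_id = donors,
                                stigma_flower_id = flowers$flower_id[i],
                                bout_id = bout_id, visit_index = v,
                                stringsAsFactors = FALSE)
    }
    cohorts[[length(cohorts) + 1L]] <-
      list(donor = flowers$genet_id[i], flower = flowers$flower_id[i],
           remaining = tr$grains_per_pickup)
  }
  ev <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(grain_id = character(0), true_donor_id = character(0),
                     stigma_flower_id = character(0), bout_id = character(0),
                     visit_index = integer(0), stringsAsFactors = FALSE)
  list(visits = data.frame(bout_id = bout_id,
                           pollinator = config$pollinator,
                           visit_order = seq_along(visits),
                           flower_id = flowers$flower_id[visits],
                           stringsAsFactors = FALSE),
       events = ev)
}

#' Apply single-pollen genotyping noise to deposition events
#'
#' Each grain's haploid genotype is one uniformly chosen allele per donor
#' locus (an independent meiosis per grain). A typing error replaces an
#' observed allele with a random panel allele at rate \code{error}; allelic
#' dropout masks each locus at rate \code{dropout}; contamination merges a
#' grain's observation with that of another grain from the same stigma at
#' rate \code{contamination}, producing 2--3 alleles at loci where the two
#' grains differ.
#'
#' @param events deposition-event data.frame.
#' @param genotypes diploid genotype data.frame of the donors.
#' @param panel a \code{locus_panel}.
#' @param noise list(dropout, contamination, error).
#' @param seed integer seed.
#' @return long grain data.frame: grain_id, bout_id, stigma_flower_id, locus,
#'   alleles (list column).
#' @export
apply_genotyping_noise <- function(events, genotypes, panel, noise,
                                   seed = 1L) {
  set.seed(seed)
  loci <- names(panel)
  n <- nrow(events)
  if (!n)
    return(data.frame(grain_id = character(0), bout_id = character(0),
                      stigma_flower_id = character(0), locus = character(0),
                      alleles = I(list()), stringsAsFactors = FALSE))
  # donor genotype lookup matrices (genet x locus)
  genets <- unique(genotypes$genet_id)
  A1 <- matrix(NA_integer_, length(genets), length(loci),
               dimnames = list(genets, loci))
  A2 <- A1
  idx <- cbind(match(genotypes$genet_id, genets),
               match(genotypes$locus, loci))
  A1[idx] <- genotypes$allele1
  A2[idx] <- genotypes$allele2
  di <- match(events$true_donor_id, genets)
  if (anyNA(di)) stop("event donor without genotype")
  # meiosis: one allele per locus
  pick2 <- matrix(stats::runif(n * length(loci)) < 0.5, n)
  G <- ifelse(pick2, A1[di, , drop = FALSE], A2[di, , drop = FALSE])
  # typing error: replace with random panel allele
  err <- matrix(stats::runif(n * length(loci)) < noise$error, n) & !is.na(G)
  if (any(err)) {
    ec <- which(err, arr.ind = TRUE)
    G[err] <- vapply(ec[, 2], function(j) sample(panel[[j]], 1L), 1L)
  }
  # dropout
  G[matrix(stats::runif(n * length(loci)) < noise$dropout, n)] <- NA_integer_
  # observation lists, then contamination merges within stigma
  obs <- lapply(seq_len(n), function(i) {
    o <- lapply(G[i, ], function(a) if (is.na(a)) integer(0) else a)
    names(o) <- loci
    o
  })
  stig <- paste(events$bout_id, events$stigma_flower_id, sep = "\r")
  contam <- stats::runif(n) < noise$contamination
  for (i in which(contam)) {
    mates <- setdiff(which(stig == stig[i]), i)
    if (!length(mates)) next
    j <- mates[sample.int(length(mates), 1L)]
    obs[[i]] <- mapply(function(a, b) sort(unique(c(a, b))),
                       obs[[i]], obs[[j]], SIMPLIFY = FALSE)
  }
  out <- data.frame(
    grain_id = rep(events$grain_id, each = length(loci)),
    bout_id = rep(events$bout_id, each = length(loci)),
    stigma_flower_id = rep(events$stigma_flower_id, each = length(loci)),
    locus = rep(loci, n), stringsAsFactors = FALSE)
  out$alleles <- unlist(obs, recursive = FALSE, use.names = FALSE)
  out
}

#' Simulate a complete mixed-array experiment
#'
#' Generates plants, genotypes and \code{n_bouts} trip bouts (a fresh flower
#' instance per genet per bout: visited plants are replaced with fresh-stigma
#' spares between bouts, so stigma pollen never carries over across bouts),
#' transports pollen, applies genotyping noise, and returns a fully
#' cross-referenced \code{pollen_experiment} carrying the ground-truth
#' deposition table.
#'
#' @param config a \code{sim_config}.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return A \code{pollen_experiment} with \code{truth}.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = 1L) {
  seed <- as.integer(seed)
  genets <- generate_plants(config, seed = seed)
  genotypes <- generate_genotypes(config, genets, seed = seed + 1L)
  bout_ids <- sprintf("B%02d", seq_len(config$n_bouts))
  plants_l <- list(); visits_l <- list(); events_l <- list(); avail_l <- list()
  for (k in seq_along(bout_ids)) {
    flowers <- genets
    flowers$flower_id <- sprintf("%s.%s", genets$genet_id, bout_ids[k])
    plants_l[[k]] <- flowers
    sim <- simulate_bout(flowers, config, bout_id = bout_ids[k],
                         seed = seed + 100L + k)
    visits_l[[k]] <- sim$visits
    events_l[[k]] <- sim$events
    avail_l[[k]] <- data.frame(bout_id = bout_ids[k],
                               flower_id = flowers$flower_id,
                               stringsAsFactors = FALSE)
  }
  plants <- do.call(rbind, plants_l)
  plants <- plants[, c("genet_id", "flower_id", "class", trait_names())]
  bouts <- do.call(rbind, visits_l)
  events <- do.call(rbind, events_l)
  grains <- apply_genotyping_noise(events, genotypes, config$panel,
                                   config$noise, seed = seed + 2L)
  pollen_experiment(plants, genotypes, bouts, grains, config$panel,
                    truth = events, availability = do.call(rbind, avail_l))
}
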