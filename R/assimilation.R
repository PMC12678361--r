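#' Default calibration parameter specifications
#'
#' The seven quantities re-estimated by assimilation — three management
#' practices and four genotype traits — with their initial values and search
#' ranges.
#'
#' @param free Optional character vector restricting the spec to a subset of
#'   parameter names (the remaining quantities stay at the base management /
#'   cultivar values during assimilation).
#' @return Data frame with columns name, initial, lower, upper.
#' @export
default_parameter_specs <- function(free = NULL) {
  specs <- data.frame(
    name    = c("plant_density", "irrigation", "fertilization",
                "p1d", "phint", "rdgs", "slpf"),
    initial = c(350, 150, 200, 50, 100, 3.0, 1.0),
    lower   = c(300,  90,   0, 30,  90, 2.5, 0.8),
    upper   = c(400, 240, 400, 70, 120, 3.5, 1.0),
    stringsAsFactors = FALSE
  )
  if (!is.null(free)) {
    bad <- setdiff(free, specs$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    specs <- specs[specs$name %in% free, , drop = FALSE]
    rownames(specs) <- NULL
  }
  specs
}

validate_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("name", "initial", "lower", "upper") %in% names(specs)))
  if (nrow(specs) == 0) stop("empty parameter spec list")
  bad <- specs$lower > specs$initial | specs$initial > specs$upper
  if (any(bad)) {
    stop("parameter spec out of order for: ",
         paste(specs$name[bad], collapse = ", "))
  }
  specs
}

#' Swarm configuration
#'
#' Defaults follow the reference setup: 25 particles, cognitive and social
#' learning factors both 2.0, 100 iterations, initial velocities about 10%
#' of each parameter's dynamic range. The printed velocity update carries no
#' inertia weight, i.e. w = 1; because w = 1 swarms can diverge, velocities
#' are re-clamped to the initialization fraction of the range at every step.
#'
#' @param n_particles Swarm size.
#' @param c1,c2 Cognitive and social learning factors.
#' @param max_iterations Iteration cap.
#' @param initial_velocity_fraction Fraction of each range bounding initial
#'   (and subsequent) velocity magnitudes.
#' @param inertia_weight Multiplier w on the previous velocity.
#' @param convergence_tolerance Stop early when the best cost improves by
#'   less than this over `patience` consecutive iterations.
#' @param patience Window length for the early-stop rule.
#' @param seed Integer seed for swarm randomness.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 25, c1 = 2.0, c2 = 2.0,
                         max_iterations = 100,
                         initial_velocity_fraction = 0.10,
                         inertia_weight = 1.0,
                         convergence_tolerance = 1e-6, patience = 10,
                         seed = 1L) {
  stopifnot(n_particles >= 1, c1 > 0, c2 > 0, max_iterations >= 1,
            initial_velocity_fraction > 0, initial_velocity_fraction <= 1,
            inertia_weight > 0, convergence_tolerance >= 0, patience >= 1)
  structure(list(n_particles = as.integer(n_particles), c1 = c1, c2 = c2,
                 max_iterations = as.integer(max_iterations),
                 initial_velocity_fraction = initial_velocity_fraction,
                 inertia_weight = inertia_weight,
                 convergence_tolerance = convergence_tolerance,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "swarm_config")
}

#' Assimilation cost: mean relative squared error
#'
#' J = (1/m) * sum_i ((AGBs_i - AGBr_i) / AGBr_i)^2, comparing the simulated
#' trajectory against remote-sensing AGB at the m observed stages.
#'
#' @param agb_simulated,agb_observed Equal-length vectors, t ha-1; all
#'   observed values must be positive (relative error is undefined at 0).
#' @return The scalar cost J.
#' @export
#' @examples
#' fitness_j(c(5, 6), c(4, 6))  # 0.03125
fitness_j <- function(agb_simulated, agb_observed) {
  if (length(agb_simulated) != length(agb_observed)) {
    stop("fitness_j: length mismatch")
  }
  if (length(agb_observed) < 1) stop("fitness_j: empty input")
  if (any(agb_observed <= 0)) {
    stop("fitness_j: observed AGB must be positive")
  }
  mean(((agb_simulated - agb_observed) / agb_observed)^2)
}

#' Initialize a particle swarm over the parameter space
#'
#' One particle is seeded at the spec's initial values (so the calibrated
#' starting point is always evaluated); the rest are uniform within bounds.
#' Velocity components are uniform in +/- fraction x range.
#'
#' @param specs Parameter spec data frame (see [default_parameter_specs()]).
#' @param config A [swarm_config()]. The caller owns the RNG state; seed
#'   before calling for reproducibility.
#' @return List with matrices `position`, `velocity` (n_particles x d),
#'   `pbest_position`, and vectors `pbest_cost` (initialized to Inf).
#' @export
initialize_swarm <- function(specs, config) {
  specs <- validate_specs(specs)
  d <- nrow(specs); np <- config$n_particles
  rng <- specs$upper - specs$lower
  pos <- matrix(stats::runif(np * d), np, d)
  pos <- sweep(sweep(pos, 2, rng, "*"), 2, specs$lower, "+")
  pos[1, ] <- specs$initial
  vmax <- config$initial_velocity_fraction * rng
  vel <- matrix(stats::runif(np * d, -1, 1), np, d)
  vel <- sweep(vel, 2, vmax, "*")
  colnames(pos) <- colnames(vel) <- specs$name
  list(position = pos, velocity = vel,
       pbest_position = pos, pbest_cost = rep(Inf, np))
}

#' One particle velocity/position update
#'
#' v' = w v + c1 xi (pbest - x) + c2 eta (gbest - x); x' = x + v'. The new
#' position is clamped to bounds with velocity zeroed in clamped dimensions,
#' and |v'| is capped at the initialization fraction of each range.
#'
#' @param position,velocity,pbest,gbest Numeric d-vectors.
#' @param specs Parameter spec data frame (bounds).
#' @param config A [swarm_config()].
#' @param xi,eta Uniform(0,1) draws, one per dimension.
#' @return List with updated `position` and `velocity`.
#' @export
update_particle <- function(position, velocity, pbest, gbest, specs, config,
                            xi, eta) {
  if (any(xi < 0 | xi > 1) || any(eta < 0 | eta > 1)) {
    stop("update_particle: xi, eta must lie in [0, 1]")
  }
  v <- config$inertia_weight * velocity +
    config$c1 * xi * (pbest - position) +
    config$c2 * eta * (gbest - position)
  vmax <- config$initial_velocity_fraction * (specs$upper - specs$lower)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- position + v
  lo_hit <- x < specs$lower; hi_hit <- x > specs$upper
  x[lo_hit] <- specs$lower[lo_hit]; x[hi_hit] <- specs$upper[hi_hit]
  v[lo_hit | hi_hit] <- 0
  list(position = x, velocity = v)
}

# Map a named position vector onto management/cultivar objects.
# "fertilization" is the season total N, split equally between the basal and
# the jointing topdressing events (matching the trial design); "irrigation"
# rescales irrigation events to the given seasonal total.
apply_parameters <- function(position, mgmt, cultivar) {
  nm <- names(position)
  if ("plant_density" %in% nm) mgmt$plant_density <- position[["plant_density"]]
  if ("irrigation" %in% nm && nrow(mgmt$irrigation_events) > 0) {
    tot <- sum(mgmt$irrigation_events$amount)
    if (tot > 0) {
      mgmt$irrigation_events$amount <-
        mgmt$irrigation_events$amount * position[["irrigation"]] / tot
    } else {
      mgmt$irrigation_events$amount <-
        rep(position[["irrigation"]] / nrow(mgmt$irrigation_events),
            nrow(mgmt$irrigation_events))
    }
  }
  if ("fertilization" %in% nm) {
    fe <- mgmt$fertilization_events
    half <- position[["fertilization"]] / 2
    if (!any(fe$type == "basal")) {
      fe <- rbind(fe, data.frame(date = mgmt$sowing_date, amount = 0,
                                 type = "basal"))
    }
    if (!any(fe$type == "topdress")) {
      # no topdressing event declared: place one at a nominal jointing date
      fe <- rbind(fe, data.frame(date = mgmt$sowing_date + 170, amount = 0,
                                 type = "topdress"))
    }
    fe$amount[fe$type == "basal"] <- half / sum(fe$type == "basal")
    fe$amount[fe$type == "topdress"] <- half / sum(fe$type == "topdress")
    mgmt$fertilization_events <- fe
  }
  cv <- unclass(cultivar)
  for (p in intersect(nm, c("p1d", "phint", "rdgs", "slpf"))) {
    cv[[p]] <- position[[p]]
  }
  cultivar <- do.call(cultivar_params, c(cv, list(check = "clamp")))
  list(mgmt = mgmt, cultivar = cultivar)
}

#' Assimilate remote-sensing AGB into a crop model by particle swarm search
#'
#' Minimizes [fitness_j()] between the model's AGB trajectory (sampled at the
#' observation dates) and the remote-sensing AGB estimates, over the
#' parameters named in `specs`. The best parameter set is then used to re-run
#' the model, whose output is returned alongside the swarm diagnostics.
#'
#' @param observations Data frame with columns `date` and `agb` (t ha-1):
#'   remote-sensing estimates at the key growth stages.
#' @param weather,soil,mgmt,cultivar Baseline season inputs; parameters in
#'   `specs` override the corresponding management/cultivar quantities.
#' @param specs Parameter specs, default all seven of
#'   [default_parameter_specs()].
#' @param config A [swarm_config()]; its `seed` drives all swarm randomness.
#' @param model Crop-model function `(weather, soil, mgmt, cultivar)`;
#'   default the registered surrogate.
#' @param verbose Print per-iteration best cost.
#' @return An `assimilation_result`: `best_position` (named), `best_cost`,
#'   `cost_trajectory` (best J after each iteration, element 1 = after
#'   initial evaluation), `iterations`, `simulation` (re-run at the optimum),
#'   `config`, `specs`.
#' @export
assimilate <- function(observations, weather, soil, mgmt, cultivar,
                       specs = default_parameter_specs(),
                       config = swarm_config(),
                       model = get_crop_model("surrogate"),
                       verbose = FALSE) {
  specs <- validate_specs(specs)
  stopifnot(is.data.frame(observations),
            all(c("date", "agb") %in% names(observations)))
  observations$date <- as.Date(observations$date)
  weather <- validate_weather(weather, latitude = mgmt$latitude)

  probe <- model(weather, soil, mgmt, cultivar)
  idx <- match(observations$date, probe$days$date)
  if (anyNA(idx)) {
    stop("observation date(s) outside the simulated season: ",
         paste(observations$date[is.na(idx)], collapse = ", "))
  }
  obs <- observations$agb

  cost_of <- function(position) {
    ap <- apply_parameters(position, mgmt, cultivar)
    sim <- model(weather, soil, ap$mgmt, ap$cultivar)
    fitness_j(sim$days$agb[idx], obs)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  swarm <- initialize_swarm(specs, config)
  np <- config$n_particles; d <- nrow(specs)

  gbest_cost <- Inf; gbest <- swarm$position[1, ]
  evaluate_all <- function() {
    for (i in seq_len(np)) {
      ci <- cost_of(swarm$position[i, ])
      if (ci < swarm$pbest_cost[i]) {
        swarm$pbest_cost[i] <<- ci
        swarm$pbest_position[i, ] <<- swarm$position[i, ]
      }
      if (ci < gbest_cost) {
        gbest_cost <<- ci; gbest <<- swarm$position[i, ]
      }
    }
  }

  evaluate_all()
  traj <- gbest_cost
  stall <- 0L; iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    prev <- gbest_cost
    for (i in seq_len(np)) {
      up <- update_particle(swarm$position[i, ], swarm$velocity[i, ],
                            swarm$pbest_position[i, ], gbest, specs, config,
                            xi = stats::runif(d), eta = stats::runif(d))
      swarm$position[i, ] <- up$position
      swarm$velocity[i, ] <- up$velocity
    }
    evaluate_all()
    traj <- c(traj, gbest_cost)
    if (verbose) message(sprintf("iter %3d: best J = %.6g", iter, gbest_cost))
    stall <- if (prev - gbest_cost < config$convergence_tolerance)
      stall + 1L else 0L
    if (stall >= config$patience) break
  }

  best <- stats::setNames(as.numeric(gbest), specs$name)
  ap <- apply_parameters(best, mgmt, cultivar)
  structure(list(best_position = best, best_cost = gbest_cost,
                 cost_trajectory = traj, iterations = iter,
                 simulation = model(weather, soil, ap$mgmt, ap$cultivar),
                 mgmt = ap$mgmt, cultivar = ap$cultivar,
                 config = config, specs = specs),
            class = "assimilation_result")
}

#' @export
print.assimilation_result <- function(x, ...) {
  cat(sprintf("PSO assimilation: best J = %.6g after %d iteration(s)\n",
              x$best_cost, x$iterations))
  print(round(x$best_position, 3))
  invisible(x)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
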