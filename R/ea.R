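# Evolutionary search over Izhikevich parameters (and coupling) against a
# phenotype spec. Generational EA: tournament selection, blend crossover,
# unbounded Gaussian mutation (only the physical parameter invariants are
# repaired), elitism, class-aware dynamic feature weights in the objective.

#' Evolutionary-search configuration
#'
#' @param pop_size Population size; `NULL` picks 240 when the spec's targets
#'   span more than one class (complex phenotype) and 120 otherwise.
#' @param generations Generation budget.
#' @param tournament Tournament size for selection.
#' @param cx_prob Per-pair crossover probability (blend crossover).
#' @param cx_alpha Blend-crossover expansion factor.
#' @param mut_prob Per-gene mutation probability.
#' @param mut_sigma_frac Gaussian mutation s.d. as a fraction of each gene's
#'   initialization-box width (the mutation itself is unbounded).
#' @param elitism Number of best individuals copied unchanged.
#' @param immigrants Fraction of each new generation replaced by fresh
#'   draws from the class boxes (diversity maintenance against premature
#'   convergence).
#' @param seed RNG seed, recorded in the fit object.
#' @param boxes Class-subregion initialization boxes, see
#'   [default_class_boxes()].
#' @param mismatch_penalty Error added per pattern whose class does not match
#'   the target (on top of the boosted feature weights). It must exceed the
#'   typical residual feature error, or selection will happily keep
#'   well-fitting models of the wrong class.
#' @param rebound_penalty Error added when required rebound spiking is absent.
#' @param base_weights Named base feature weights `W_f` (features not named
#'   default to 1). The default up-weights `sfa`, whose natural scale
#'   (~0.01-0.2) would otherwise contribute negligibly to the log error
#'   next to millisecond-scale features, and the integer counts, which
#'   acceptance requires exactly (a one-off count must cost more than a
#'   marginal sfa error, or selection trades the count away).
#' @param boost Dynamic-weight boost factor, see [dynamic_weights()].
#' @param stop_after Stop early once this many distinct accepted models have
#'   been collected (`Inf` to always run the full budget).
#' @param polish_every,polish_iters Period (in generations) and iteration
#'   budget of the local Nelder-Mead refinement of the incumbent best genome
#'   (memetic step; 0 disables). The refinement minimizes the distance to
#'   the acceptance region (per-feature discrepancy in units of its
#'   tolerance, zero inside), so it pulls marginal candidates over the
#'   acceptance boundary; the polished genome re-enters the population and
#'   is screened for acceptance like any other.
#' @param probe_tol Bisection tolerance (nA) for the rheobase probes inside
#'   the objective (acceptance re-probes at full precision).
#' @return An `ea_config` list.
#' @export
ea_config <- function(pop_size = NULL, generations = 60, tournament = 3,
                      cx_prob = 0.7, cx_alpha = 0.5, mut_prob = 0.25,
                      mut_sigma_frac = 0.1, elitism = 1, immigrants = 0.08,
                      seed = 1,
                      boxes = default_class_boxes(),
                      mismatch_penalty = 20, rebound_penalty = 20,
                      base_weights = c(sfa = 50, n_isis = 10, n_bursts = 10),
                      boost = 10,
                      stop_after = 1, probe_tol = 0.005,
                      polish_every = 20, polish_iters = 150) {
  structure(list(pop_size = pop_size, generations = generations,
                 tournament = tournament, cx_prob = cx_prob,
                 cx_alpha = cx_alpha, mut_prob = mut_prob,
                 mut_sigma_frac = mut_sigma_frac, elitism = elitism,
                 immigrants = immigrants, seed = seed, boxes = boxes,
                 mismatch_penalty = mismatch_penalty,
                 rebound_penalty = rebound_penalty,
                 base_weights = base_weights, boost = boost,
                 stop_after = stop_after, probe_tol = probe_tol,
                 polish_every = polish_every, polish_iters = polish_iters),
            class = "ea_config")
}

# ---- genome layout -------------------------------------------------------

genome_layout <- function(spec) {
  nc <- spec$n_compartments
  n_unknown <- sum(vapply(spec$patterns, function(p) is.na(p$amplitude_nA),
                          logical(1)))
  # soma: 9 params; each extra compartment: 8 params (shared Vr) + G + P
  list(nc = nc,
       n_genes = 9 + (nc - 1) * 10 + n_unknown,
       unknown_idx = which(vapply(spec$patterns,
                                  function(p) is.na(p$amplitude_nA),
                                  logical(1))))
}

DEND_PARAMS <- c("C", "k", "Vt", "Vpeak", "Vmin", "a", "b", "d")

decode_genome <- function(genome, spec) {
  lay <- genome_layout(spec)
  soma <- genome[1:9]
  names(soma) <- param_names
  comps <- list(soma = do.call(izhi_params, as.list(soma)))
  edges <- NULL
  pos <- 9
  if (lay$nc > 1) {
    edges <- data.frame(prox = integer(0), dist = integer(0),
                        G = numeric(0), P = numeric(0))
    for (j in 2:lay$nc) {
      g <- genome[pos + 1:10]
      p <- as.list(setNames(g[1:8], DEND_PARAMS))
      p$Vr <- soma[["Vr"]]
      comps[[paste0("dend", j - 1)]] <- do.call(izhi_params, p)
      edges <- rbind(edges, data.frame(prox = j - 1, dist = j,
                                       G = g[9], P = g[10]))
      pos <- pos + 10
    }
  }
  currents_pA <- vapply(spec$patterns, function(p)
    if (is.na(p$amplitude_nA)) NA_real_ else p$amplitude_nA * 1000,
    numeric(1))
  if (length(lay$unknown_idx)) {
    currents_pA[lay$unknown_idx] <- genome[pos + seq_along(lay$unknown_idx)]
  }
  list(model = compartment_model(comps, edges), currents_pA = currents_pA)
}

# enforce the physical invariants after unbounded mutation/crossover;
# the repair is minimal and deterministic
repair_genome <- function(genome, spec) {
  lay <- genome_layout(spec)
  fix_params <- function(g, vr) {
    # g: C,k,(Vr),Vt,Vpeak,Vmin,a,b,d layout depending on compartment
    g
  }
  g <- genome
  # soma block: C k Vr Vt Vpeak Vmin a b d
  g[1] <- max(g[1], 5)            # C
  g[2] <- max(g[2], 0.05)         # k
  g[4] <- max(g[4], g[3] + 2)     # Vt > Vr
  g[5] <- max(g[5], g[4] + 10)    # Vpeak > Vt
  g[6] <- min(g[6], g[5] - 5)     # Vmin < Vpeak
  g[7] <- min(max(g[7], 1e-4), 2) # a
  pos <- 9
  if (lay$nc > 1) {
    for (j in 2:lay$nc) {
      i <- pos
      g[i + 1] <- max(g[i + 1], 5)
      g[i + 2] <- max(g[i + 2], 0.05)
      g[i + 3] <- max(g[i + 3], g[3] + 2)        # Vt > shared Vr
      g[i + 4] <- max(g[i + 4], g[i + 3] + 10)   # Vpeak
      g[i + 5] <- min(g[i + 5], g[i + 4] - 5)    # Vmin
      g[i + 6] <- min(max(g[i + 6], 1e-4), 2)    # a
      g[i + 9] <- max(g[i + 9], 0)               # G
      g[i + 10] <- min(max(g[i + 10], 0), 1)     # P
      pos <- pos + 10
    }
  }
  if (length(lay$unknown_idx)) {
    for (k in seq_along(lay$unknown_idx)) {
      br <- spec$patterns[[lay$unknown_idx[k]]]$bracket_nA * 1000
      g[pos + k] <- min(max(g[pos + k], br[1]), br[2])
    }
  }
  g
}

# ---- objective -----------------------------------------------------------

needs_series <- function(spec) {
  any(vapply(spec$patterns, function(p)
    any(c(p$label$transients, p$label$steady) %in% c("TSWB", "PSWB"),
        na.rm = TRUE), logical(1)))
}

evaluate_genome <- function(genome, spec, cfg, dt = 0.1) {
  dec <- tryCatch(decode_genome(genome, spec), error = function(e) NULL)
  if (is.null(dec)) return(list(fitness = 1e9, evals = NULL))
  model <- dec$model
  record <- needs_series(spec)
  total <- 0
  evals <- vector("list", length(spec$patterns))
  for (i in seq_along(spec$patterns)) {
    p <- spec$patterns[[i]]
    st <- step_stimulus(dec$currents_pA[i], onset = p$onset,
                        duration = p$duration, target = model$soma)
    res <- tryCatch({
      tr <- simulate_model(model, st, dt = dt, record = record)
      classify_trace(tr, st, spec$thresholds,
                     slow_ahp = if (record) NULL else FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) return(list(fitness = 1e9, evals = NULL))
    w <- dynamic_weights(p$label, res$label, base = cfg$base_weights,
                         boost = cfg$boost)
    err <- pattern_error(p$features, res$features, weights = w,
                         family = feature_family(p$label))
    if (!label_match(res$label, p$label,
                     allow_rasp_exception = spec$n_compartments == 1))
      err <- err + cfg$mismatch_penalty
    total <- total + err
    evals[[i]] <- res
  }
  rebound_ok <- TRUE
  if (!is.null(spec$rebound_nA)) {
    st <- step_stimulus(spec$rebound_nA, onset = 100, duration = 500,
                        total_time = 1100, target = model$soma, units = "nA")
    tr <- tryCatch(simulate_model(model, st, dt = dt, record = FALSE),
                   error = function(e) NULL)
    rebound_ok <- !is.null(tr) && any(spike_times(tr) > 600)
    if (!rebound_ok) total <- total + cfg$rebound_penalty
  }
  constraints <- NULL
  if (spec$n_compartments > 1) {
    constraints <- tryCatch(
      probe_constraints_fast(model, cfg$probe_tol, dt),
      error = function(e) NULL)
    total <- if (is.null(constraints)) total + 20 else
      total + sum(constraints)
  }
  list(fitness = total, evals = evals, rebound_ok = rebound_ok,
       constraints = constraints, model = model,
       currents_pA = dec$currents_pA)
}

# cheap constraint errors for the objective (coarser rheobase tolerance,
# shorter probe windows); acceptance re-probes at full precision
probe_constraints_fast <- function(model, tol, dt) {
  nc <- n_compartments(model)
  rheo <- vapply(model$compartments, function(p)
    find_rheobase(p, tol = tol, dt = dt, duration = 500), numeric(1))
  vdef <- vapply(model$compartments, function(p)
    voltage_deflection(p, -0.05, dt = dt, duration = 500), numeric(1))
  dend <- setdiff(seq_len(nc), model$soma)
  R <- vapply(dend, function(j) {
    r <- propagation_ratio(model, j, events = c(200, 300, 400), dt = dt)
    if (is.na(r)) 0 else min(r, 1)
  }, numeric(1))
  ep <- vapply(dend, function(j)
    tryCatch(epsp_amplitude(model, j, dt = dt), error = function(e) 10),
    numeric(1))
  ce <- constraint_errors(rheo[model$soma], rheo[dend],
                          vdef[model$soma], vdef[dend], R, ep)
  c(rheo = sum(ce$rheo), vdef = sum(ce$vdef), prop = sum(ce$prop),
    epsp = sum(ce$epsp))
}

# distance to the acceptance region: per-feature discrepancy in units of
# its tolerance (0 inside), large penalties for class mismatch; the local
# refinement minimizes this margin rather than the raw log error
acceptance_margin <- function(ev, spec, tol) {
  if (is.null(ev$evals)) return(1e9)
  total <- 0
  for (i in seq_along(spec$patterns)) {
    p <- spec$patterns[[i]]
    res <- ev$evals[[i]]
    if (!label_match(res$label, p$label,
                     allow_rasp_exception = spec$n_compartments == 1))
      total <- total + 100
    for (f in names(p$features)) {
      tv <- p$features[[f]]
      mv <- feature_value(res$features, f)
      if (is.null(mv) || all(is.na(mv)) || length(mv) != length(tv)) {
        total <- total + 100
      } else if (f %in% c("n_isis", "n_bursts", "b_n_isis")) {
        total <- total + 10 * sum(abs(mv - tv))
      } else if (f == "sfa") {
        total <- total + sum(pmax(0, abs(mv - tv) / tol$sfa_abs - 1))
      } else {
        tband <- pmax(tol$time_frac * abs(tv), tol$time_abs_ms)
        total <- total + sum(pmax(0, abs(mv - tv) / tband - 1))
      }
    }
  }
  if (!ev$rebound_ok) total <- total + 100
  if (!is.null(ev$constraints)) total <- total + 10 * sum(ev$constraints)
  total
}

# cheap pre-screen for acceptance using quantities already computed
screen_accept <- function(ev, spec, tol) {
  if (is.null(ev$evals)) return(FALSE)
  if (!ev$rebound_ok) return(FALSE)
  if (!is.null(ev$constraints) && any(ev$constraints > 0)) return(FALSE)
  for (i in seq_along(spec$patterns)) {
    p <- spec$patterns[[i]]
    res <- ev$evals[[i]]
    if (!label_match(res$label, p$label,
                     allow_rasp_exception = spec$n_compartments == 1))
      return(FALSE)
    for (f in names(p$features)) {
      if (!feature_within_tol(f, p$features[[f]],
                              feature_value(res$features, f), tol))
        return(FALSE)
    }
  }
  TRUE
}

# ---- initialization ------------------------------------------------------

sample_box <- function(box) {
  stats::runif(nrow(box), box[, 1], box[, 2])
}

init_genome <- function(spec, cfg, family) {
  box <- cfg$boxes[[family]]
  if (is.null(box)) box <- cfg$boxes[["broad"]]
  # rebound spiking needs a resonator (b > 0); seed b there when required
  if (!is.null(spec$rebound_nA)) box["b", ] <- c(1, 25)
  g <- sample_box(box)
  if (spec$n_compartments > 1) {
    cb <- coupling_box()
    for (j in 2:spec$n_compartments) {
      # seed dendrites near the somatic draw (relative jitter): the
      # constraint-feasible region lies close to electrotonic uniformity
      dend <- g[c(1, 2, 4, 5, 6, 7, 8, 9)] *
        stats::runif(8, 0.7, 1.3)                     # drop Vr (shared)
      g <- c(g, dend, stats::runif(1, cb["G", 1], cb["G", 2]),
             stats::runif(1, cb["P", 1], cb["P", 2]))
    }
  }
  lay <- genome_layout(spec)
  for (i in lay$unknown_idx) {
    br <- spec$patterns[[i]]$bracket_nA * 1000
    g <- c(g, stats::runif(1, br[1], br[2]))
  }
  repair_genome(g, spec)
}

#' Initialize an EA population from class subregions
#'
#' Individuals are drawn uniformly from the initialization boxes of all
#' target classes of the phenotype, cycling through the classes so each
#' contributes about equally. Draws are screened for viability: a candidate
#' must produce at least two spikes at the weakest target current (up to 20
#' redraws), so the search starts from excitability-compatible material
#' rather than from silent corners of the box.
#'
#' @param spec A [phenotype_spec()].
#' @param cfg An [ea_config()].
#' @param n Population size.
#' @return List of genomes (numeric vectors).
#' @export
initialize_population <- function(spec, cfg, n) {
  fams <- vapply(spec$patterns, function(p) class_box_family(p$label),
                 character(1))
  fams <- unique(fams)
  amps <- vapply(spec$patterns, function(p)
    if (is.na(p$amplitude_nA)) mean(p$bracket_nA) * 1000
    else p$amplitude_nA * 1000, numeric(1))
  i_min <- which.min(amps)
  p_min <- spec$patterns[[i_min]]
  viable <- function(g) {
    dec <- tryCatch(decode_genome(g, spec), error = function(e) NULL)
    if (is.null(dec)) return(FALSE)
    st <- step_stimulus(amps[i_min], onset = p_min$onset,
                        duration = p_min$duration, target = dec$model$soma)
    tr <- tryCatch(simulate_model(dec$model, st, record = FALSE),
                   error = function(e) NULL)
    !is.null(tr) && length(spike_times(tr)) >= 2
  }
  lapply(seq_len(n), function(i) {
    fam <- fams[(i - 1) %% length(fams) + 1]
    g <- init_genome(spec, cfg, fam)
    tries <- 0
    while (!viable(g) && tries < 20) {
      g <- init_genome(spec, cfg, fam)
      tries <- tries + 1
    }
    g
  })
}

# per-gene mutation scale: box width of the broad box (plus coupling genes)
mutation_scale <- function(spec, cfg) {
  box <- cfg$boxes[["broad"]]
  w <- box[, 2] - box[, 1]
  if (spec$n_compartments > 1) {
    cb <- coupling_box()
    for (j in 2:spec$n_compartments)
      w <- c(w, w[c(1, 2, 4, 5, 6, 7, 8, 9)],
             cb["G", 2] - cb["G", 1], cb["P", 2] - cb["P", 1])
  }
  lay <- genome_layout(spec)
  for (i in lay$unknown_idx) {
    br <- spec$patterns[[i]]$bracket_nA * 1000
    w <- c(w, br[2] - br[1])
  }
  w * cfg$mut_sigma_frac
}

# ---- the search ----------------------------------------------------------

#' Fit a phenotype with the evolutionary algorithm
#'
#' Runs a generational EA against the spec's objective (feature-weighted log
#' error with dynamic class-mismatch weights, plus dendritic constraint
#' errors for multi-compartment layouts and a rebound penalty when the spec
#' requires rebound spiking). Every individual ever evaluated that passes the
#' full acceptance check is collected, deduplicated, into the model cloud.
#'
#' @param spec A [phenotype_spec()].
#' @param cfg An [ea_config()].
#' @param tol Acceptance tolerances, see [accept_tolerances()].
#' @param dt Integration step (ms).
#' @param verbose Print per-generation progress.
#' @return An `izhi_fit` object: `cloud` (tibble of accepted models with
#'   their parameters, currents and error), `best_model`, `best_error`,
#'   `log` (per-generation best/mean error), `accepted` (list of
#'   [compartment_model()]s), plus the spec, config and seed.
#' @export
fit_phenotype <- function(spec, cfg = ea_config(), tol = accept_tolerances(),
                          dt = 0.1, verbose = FALSE) {
  stopifnot(inherits(spec, "phenotype_spec"), inherits(cfg, "ea_config"))
  n_classes <- length(unique(vapply(spec$patterns,
                                    function(p) format(p$label),
                                    character(1))))
  npop <- cfg$pop_size
  if (is.null(npop)) npop <- if (n_classes > 1) 240 else 120
  set.seed(cfg$seed)
  pop <- initialize_population(spec, cfg, npop)
  sigma <- mutation_scale(spec, cfg)
  accepted <- list()
  seen <- character(0)
  log <- vector("list", cfg$generations)
  best_genome <- NULL
  best_fit <- Inf
  best_ever <- list()

  consider <- function(genome, ev) {
    key <- paste(signif(genome, 8), collapse = ",")
    if (key %in% seen) return(invisible(NULL))
    if (screen_accept(ev, spec, tol)) {
      dec <- decode_genome(genome, spec)
      if (accept_model(dec$model, spec, dec$currents_pA, tol, dt)) {
        seen <<- c(seen, key)
        accepted[[length(accepted) + 1]] <<- list(
          model = dec$model, currents_pA = dec$currents_pA,
          genome = genome, fitness = ev$fitness)
      }
    }
    invisible(NULL)
  }

  for (gen in seq_len(cfg$generations)) {
    evs <- lapply(pop, evaluate_genome, spec = spec, cfg = cfg, dt = dt)
    fits <- vapply(evs, `[[`, numeric(1), "fitness")
    for (i in seq_along(pop)) consider(pop[[i]], evs[[i]])
    gb <- which.min(fits)
    if (fits[gb] < best_fit) {
      best_fit <- fits[gb]
      best_genome <- pop[[gb]]
      best_ever <- evs[[gb]]
    }
    log[[gen]] <- tibble::tibble(generation = gen, best = best_fit,
                                 mean = mean(fits[is.finite(fits)]),
                                 n_accepted = length(accepted))
    if (verbose)
      message(sprintf("gen %3d  best %.4f  mean %.2f  accepted %d",
                      gen, best_fit, mean(fits), length(accepted)))
    if (length(accepted) >= cfg$stop_after) break
    # periodic local refinement of the incumbent (memetic step)
    if (cfg$polish_iters > 0 && cfg$polish_every > 0 &&
        gen %% cfg$polish_every == 0 && is.finite(best_fit)) {
      pol <- stats::optim(best_genome, function(g) {
        ev <- evaluate_genome(repair_genome(g, spec), spec, cfg, dt)
        acceptance_margin(ev, spec, tol)
      }, method = "Nelder-Mead",
      control = list(maxit = cfg$polish_iters, warn.1d.NelderMead = FALSE))
      pg <- repair_genome(pol$par, spec)
      pev <- evaluate_genome(pg, spec, cfg, dt)
      consider(pg, pev)
      if (pev$fitness < best_fit) {
        best_fit <- pev$fitness
        best_genome <- pg
        best_ever <- pev
      }
      # polished solution replaces the current worst individual
      pop[[which.max(fits)]] <- pg
      if (length(accepted) >= cfg$stop_after) break
    }
    if (gen == cfg$generations) break
    # selection (tournament), elitism, blend crossover, Gaussian mutation
    ord <- order(fits)
    elite <- pop[ord[seq_len(min(cfg$elitism, npop))]]
    fams <- unique(vapply(spec$patterns, function(p)
      class_box_family(p$label), character(1)))
    n_imm <- min(floor(cfg$immigrants * npop), npop - length(elite))
    imm <- lapply(seq_len(n_imm), function(i)
      init_genome(spec, cfg, fams[(i - 1) %% length(fams) + 1]))
    select <- function() {
      cand <- sample.int(npop, cfg$tournament, replace = TRUE)
      pop[[cand[which.min(fits[cand])]]]
    }
    children <- vector("list", npop - length(elite) - n_imm)
    i <- 1
    while (i <= length(children)) {
      p1 <- select(); p2 <- select()
      if (stats::runif(1) < cfg$cx_prob) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        rng <- hi - lo
        c1 <- stats::runif(length(p1), lo - cfg$cx_alpha * rng,
                           hi + cfg$cx_alpha * rng)
        c2 <- stats::runif(length(p1), lo - cfg$cx_alpha * rng,
                           hi + cfg$cx_alpha * rng)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > length(children)) break
        mut <- stats::runif(length(child)) < cfg$mut_prob
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, sigma[mut])  # unbounded
        children[[i]] <- repair_genome(child, spec)
        i <- i + 1
      }
    }
    pop <- c(elite, imm, children)
  }

  log <- dplyr::bind_rows(log[!vapply(log, is.null, logical(1))])
  cloud <- if (length(accepted)) {
    purrr::map_dfr(seq_along(accepted), function(i) {
      a <- accepted[[i]]
      pm <- model_par_matrix(a$model)
      row <- tibble::tibble(model_id = i, error = a$fitness)
      for (j in seq_len(nrow(pm)))
        for (pn in param_names) {
          nm <- if (j == 1) pn else paste0(pn, "_", rownames(pm)[j])
          row[[nm]] <- pm[j, pn]
        }
      if (nrow(a$model$edges))
        for (e in seq_len(nrow(a$model$edges))) {
          row[[paste0("G_", e)]] <- a$model$edges$G[e]
          row[[paste0("P_", e)]] <- a$model$edges$P[e]
        }
      row$currents_nA <- list(a$currents_pA / 1000)
      row
    })
  } else tibble::tibble()
  best_dec <- if (!is.null(best_genome)) decode_genome(best_genome, spec)
  structure(list(spec = spec, config = cfg, tol = tol, dt = dt,
                 cloud = cloud, accepted = accepted,
                 best_model = best_dec$model,
                 best_currents_pA = best_dec$currents_pA,
                 best_error = best_fit, log = log,
                 seed = cfg$seed,
                 n_accepted = length(accepted)),
            class = "izhi_fit")
}

#' @export
print.izhi_fit <- function(x, ...) {
  cat("<izhi_fit> ", x$spec$name, ": ", x$n_accepted,
      " accepted model(s), best error ", signif(x$best_error, 5),
      " after ", max(x$log$generation), " generation(s) [seed ", x$seed,
      "]\n", sep = "")
  invisible(x)
}

#' @rdname fit_phenotype
#' @param x An `izhi_fit`.
#' @param ... Unused.
#' @export
tidy.izhi_fit <- function(x, ...) x$cloud

#' @rdname fit_phenotype
#' @export
glance.izhi_fit <- function(x, ...) {
  tibble::tibble(phenotype = x$spec$name, n_accepted = x$n_accepted,
                 best_error = x$best_error,
                 generations = max(x$log$generation), seed = x$seed)
}

#' @rdname fit_phenotype
#' @param object An `izhi_fit`.
#' @export
autoplot.izhi_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("best", "mean"),
                            names_to = "series", values_to = "error")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$error,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "objective (log scale)",
                  title = object$spec$name) +
    ggplot2::theme_minimal()
}
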