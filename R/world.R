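# Synthetic world: procedural gravel backgrounds, a simulated observer,
# and the closed-loop runner that exercises the whole pipeline (render ->
# arena -> attacks -> ranks -> selection -> breeding) with no field data.

#' Specification of a procedural gravel background
#'
#' Band-limited colour noise around a mean CIELAB colour, optionally
#' overlaid with low-frequency "furrows": meandering sinusoidal luminance
#' ridges emulating a 3D-structured gravel surface (amplitude 0 gives the
#' smooth treatment). Deterministic for a given seed.
#'
#' @param size `c(width, height)` px.
#' @param mean_lab mean colour, CIELAB (default a mid-grey gravel tone).
#' @param texture_scale grain size in px.
#' @param texture_contrast luminance sd of the grain, in L units.
#' @param furrow_amplitude relative luminance modulation depth (>= 0).
#' @param furrow_wavelength ridge spacing in px (> 0).
#' @param seed integer seed.
#' @return object of class `background_spec`.
#' @export
background_spec <- function(size = c(512, 512),
                            mean_lab = c(55, 3, 18),
                            texture_scale = 8, texture_contrast = 8,
                            furrow_amplitude = 0,
                            furrow_wavelength = 128, seed = 1L) {
  stopifnot(furrow_amplitude >= 0, furrow_wavelength > 0,
            texture_scale > 0, length(size) == 2, all(size >= 16))
  structure(list(size = as.integer(size), mean_lab = as.numeric(mean_lab),
                 texture_scale = texture_scale,
                 texture_contrast = texture_contrast,
                 furrow_amplitude = furrow_amplitude,
                 furrow_wavelength = furrow_wavelength,
                 seed = as.integer(seed)),
            class = "background_spec")
}

#' Generate a procedural background image
#' @param spec a [background_spec()].
#' @return H x W x 3 sRGB array in \[0, 1\].
#' @export
generate_background <- function(spec) {
  w <- spec$size[1]
  h <- spec$size[2]
  seeds <- derive_seeds(spec$seed, 6)
  field <- function(s, scale) {
    f <- with_seed(s, matrix(rnorm(h * w), h, w))
    f <- gaussian_blur(f, scale / 4)
    sdf <- sd(as.vector(f))
    if (sdf > 0) f / sdf else f
  }
  fL <- field(seeds[1], spec$texture_scale)
  fa <- field(seeds[2], spec$texture_scale)
  fb <- field(seeds[3], spec$texture_scale)
  L <- spec$mean_lab[1] + spec$texture_contrast * fL
  a <- spec$mean_lab[2] + 0.5 * spec$texture_contrast * fa
  b <- spec$mean_lab[3] + 0.5 * spec$texture_contrast * fb
  if (spec$furrow_amplitude > 0) {
    theta <- with_seed(seeds[4], runif(1, 0, pi))
    x <- matrix(seq_len(w), h, w, byrow = TRUE)
    y <- matrix(seq_len(h), h, w)
    u <- x * cos(theta) + y * sin(theta)
    wander <- gaussian_blur(with_seed(seeds[5], matrix(rnorm(h * w), h, w)),
                            spec$furrow_wavelength / 2)
    sdw <- sd(as.vector(wander))
    if (sdw > 0) wander <- wander / sdw
    phase <- 2 * pi * (u + 0.25 * spec$furrow_wavelength * wander) /
      spec$furrow_wavelength
    L <- L * (1 + spec$furrow_amplitude * sin(phase))
  }
  L <- pmin(pmax(L, 0), 100)
  srgb <- lab_to_srgb(cbind(as.vector(L), as.vector(a), as.vector(b))) / 255
  out <- array(0, c(h, w, 3))
  for (c in 1:3) out[, , c] <- matrix(srgb[, c], h, w)
  out
}

#' Simulated observer model
#'
#' A stand-in for a foraging predator (or a screen-task volunteer): each
#' target's detectability is a weighted sum of camouflage metrics
#' (`delta_s`, `delta_l`, `1 - gabrat`, `pattern_difference`), and attacks
#' are drawn sequentially without replacement with probability
#' proportional to `exp(d / tau)`. As `tau -> 0` the order becomes exactly
#' descending detectability; large `tau` approaches uniform random
#' attacks. `max_attacks` truncates each group's trial (default 3 of 4,
#' matching trials that end once at least three prey per tray are taken).
#'
#' @param weights named numeric weights for `delta_s`, `delta_l`,
#'   `gabrat` (applied to 1 - GabRat) and `pattern_difference`.
#' @param tau softmax noise temperature (>= 0 finite).
#' @param max_attacks attacks per group before truncation (NA = all).
#' @return object of class `observer_model`.
#' @export
observer_model <- function(weights = c(delta_s = 1, delta_l = 1,
                                       gabrat = 0,
                                       pattern_difference = 0),
                           tau = 0.5, max_attacks = 3L) {
  w <- c(delta_s = 0, delta_l = 0, gabrat = 0, pattern_difference = 0)
  w[names(weights)] <- weights
  stopifnot(any(w > 0), is.finite(tau), tau >= 0)
  structure(list(weights = w, tau = tau,
                 max_attacks = as.integer(max_attacks)),
            class = "observer_model")
}

# detectability of metric rows under an observer
detectability <- function(metrics_row, obs) {
  w <- obs$weights
  d <- 0
  if (w["delta_s"] > 0) d <- d + w["delta_s"] * metrics_row$delta_s
  if (w["delta_l"] > 0) d <- d + w["delta_l"] * metrics_row$delta_l
  if (w["gabrat"] > 0) d <- d + w["gabrat"] * (1 - metrics_row$gabrat)
  if (w["pattern_difference"] > 0) {
    d <- d + w["pattern_difference"] * metrics_row$pattern_difference
  }
  as.numeric(d)
}

metrics_needed <- function(obs) {
  names(obs$weights)[obs$weights > 0]
}

#' Simulate the attack order within one group
#'
#' @param d detectability scores, one per prey in the group.
#' @param obs an [observer_model()].
#' @param seed integer seed.
#' @return integer vector of attacked prey indices in attack order
#'   (length `min(max_attacks, length(d))`).
#' @export
simulate_attack_order <- function(d, obs, seed) {
  n <- length(d)
  stopifnot(n >= 1)
  k <- if (is.na(obs$max_attacks)) n else min(obs$max_attacks, n)
  with_seed(seed, {
    remaining <- seq_len(n)
    order_out <- integer(0)
    for (step in seq_len(k)) {
      dr <- d[remaining]
      if (obs$tau <= 1e-12) {
        top <- which(dr == max(dr))
        pick <- if (length(top) > 1) sample(top, 1) else top
      } else {
        p <- exp((dr - max(dr)) / obs$tau)
        pick <- sample.int(length(remaining), 1, prob = p)
      }
      order_out <- c(order_out, remaining[pick])
      remaining <- remaining[-pick]
    }
    order_out
  })
}

#' Run a full closed-loop evolution experiment
#'
#' Composes every stage: a procedural background, a founder population
#' (full or background-derived narrow colour box), per-generation target
#' rendering, arena assignment, simulated attacks truncated at three per
#' tray, fitness ranks, survivor selection with the rescue rule (or the
#' random-drift control), and breeding. After the last scored generation
#' one additional unscored population is produced, accounting for the
#' final set of observer decisions. All per-generation state is persisted
#' so the run can be replayed byte for byte.
#'
#' @param cfg a [run_config()]; `cfg$selection` picks ranked vs control.
#' @param bg_spec a [background_spec()].
#' @param obs an [observer_model()].
#' @param vs a [visual_system()].
#' @param out_dir run directory to create (NULL = no files written).
#' @param colour_space `"full"` or `"narrow"` (narrow: 2 sd around the
#'   background mean colour).
#' @param target_px rendered target size, default `c(128, 96)`.
#' @param metrics_which metrics recorded per target each generation (the
#'   observer's metrics are always added).
#' @param write_png also write target PNGs (slow; default FALSE).
#' @return list of class `camo_run`: `metrics` (data.frame with
#'   `generation` column), `records` (list of `generation_record`),
#'   `final_population`, `cfg`, `box`, `dir`.
#' @export
run_closed_loop <- function(cfg, bg_spec = background_spec(),
                            obs = observer_model(),
                            vs = visual_system(), out_dir = NULL,
                            colour_space = c("full", "narrow"),
                            target_px = c(128, 96),
                            metrics_which = c("delta_s", "delta_l",
                                              "delta_s_weighted"),
                            write_png = FALSE) {
  colour_space <- match.arg(colour_space)
  bg <- generate_background(bg_spec)
  box <- if (colour_space == "narrow") {
    narrow_space_from_background(bg, k = 2)
  } else {
    cfg$box
  }
  bstat <- background_stats(bg, vs)
  metrics_all <- union(metrics_which, metrics_needed(obs))
  bg_spectrum <- if ("pattern_difference" %in% metrics_all) {
    granularity_spectrum(bg, vs = vs)
  }

  n_gen <- cfg$n_generations
  gs <- derive_seeds(cfg$seed, 4L * n_gen + 4L)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  pop <- founder_population(cfg, seed = gs[1])
  records <- list()
  prev_record <- NULL
  metrics_tab <- list()

  for (g in seq_len(n_gen) - 1L) {
    base <- 4L * g
    phenos <- lapply(pop$genomes, decode_genome, space = box)
    targets <- lapply(pop$genomes, render_target, size_px = target_px,
                      space = box)
    mrows <- do.call(rbind, lapply(seq_along(targets), function(i) {
      target_metrics(targets[[i]], phenos[[i]], bg, bstat = bstat,
                     vs = vs, which = metrics_all,
                     bg_spectrum = bg_spectrum)
    }))
    mrows <- cbind(generation = g, mrows)
    metrics_tab[[g + 1L]] <- mrows

    asg <- assign_arenas(pop, cfg, seed = gs[base + 2L])
    grouping <- default_grouping(pop, cfg)
    d <- detectability(mrows, obs)
    ids <- population_ids(pop)
    aseeds <- derive_seeds(gs[base + 3L], cfg$n_groups)
    attacks <- do.call(rbind, lapply(seq_len(cfg$n_groups), function(gr) {
      gi <- which(grouping$group == gr)
      ord <- simulate_attack_order(d[gi], obs, aseeds[gr])
      data.frame(prey_id = ids[gi][ord],
                 attack_index = seq_along(ord),
                 stringsAsFactors = FALSE)
    }))
    ranks <- ranks_from_attacks(attacks, grouping, cfg,
                                seed = gs[base + 4L])
    rec <- generation_record(pop, ranks = ranks, seed = gs[base + 1L])
    nxt <- advance_generation(rec, prev_record, cfg,
                              seed = gs[base + 5L])
    rec <- attr(nxt, "scored")
    records[[g + 1L]] <- rec
    if (!is.null(out_dir)) {
      persist_generation(out_dir, g, rec, asg, attacks,
                         write_png = write_png, targets = targets)
    }
    prev_record <- rec
    pop <- nxt$population
  }
  # final unscored population
  records[[n_gen + 1L]] <- generation_record(pop, seed = gs[4L * n_gen])
  metrics <- do.call(rbind, metrics_tab)
  if (!is.null(out_dir)) {
    persist_generation(out_dir, n_gen, records[[n_gen + 1L]], NULL, NULL)
    write.csv(metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE, quote = FALSE)
    summary <- list(
      population_size = cfg$population_size, group_size = cfg$group_size,
      n_groups = cfg$n_groups, n_generations = cfg$n_generations,
      mutation_rate = cfg$mutation_rate, mutation_sd = cfg$mutation_sd,
      selection = cfg$selection,
      min_attacked_per_group = cfg$min_attacked_per_group,
      seed = cfg$seed, colour_space = colour_space,
      target_px = target_px, metrics_which = metrics_which,
      observer = list(weights = as.list(obs$weights), tau = obs$tau,
                      max_attacks = obs$max_attacks),
      background = unclass(bg_spec)
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(metrics = metrics, records = records,
                 final_population = pop, cfg = cfg, box = box,
                 dir = out_dir),
            class = "camo_run")
}

#' @export
print.camo_run <- function(x, ...) {
  cat(sprintf(
    "camo_run: %d scored generations of %d prey (%s selection)%s\n",
    x$cfg$n_generations, x$cfg$population_size, x$cfg$selection,
    if (!is.null(x$dir)) paste0(", persisted in ", x$dir) else ""))
  invisible(x)
}

persist_generation <- function(out_dir, g, rec, asg, attacks,
                               write_png = FALSE, targets = NULL) {
  gdir <- file.path(out_dir, sprintf("gen_%03d", g))
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(genomes_to_df(rec$population$genomes, generation = g),
            file.path(gdir, "genomes.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(rec$ranks)) {
    write.csv(as.data.frame(rec$ranks), file.path(gdir, "ranks.csv"),
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(asg)) {
    export_manifest(asg, file.path(gdir, "manifest.csv"))
  }
  if (!is.null(attacks)) {
    write.csv(attacks, file.path(gdir, "attacks.csv"), row.names = FALSE,
              quote = FALSE)
  }
  jsonlite::write_json(
    list(generation = g, seed = rec$seed, survivors = rec$survivors,
         rescues = rec$rescues),
    file.path(gdir, "record.json"), auto_unbox = TRUE, digits = NA
  )
  if (write_png && !is.null(targets)) {
    tdir <- file.path(gdir, "targets")
    dir.create(tdir, showWarnings = FALSE)
    for (t in targets) {
      write_target_png(t, file.path(tdir, paste0(t$genome_id, ".png")))
    }
  }
  invisible(gdir)
}

#' Replay a persisted closed-loop run
#'
#' Re-executes a run from its stored `summary.json` into a new directory.
#' Because every stochastic step is driven by seeds stored with the run,
#' the replay reproduces `genomes.csv`, `ranks.csv` and `metrics.csv`
#' byte for byte.
#'
#' @param run_dir directory of an existing run.
#' @param out_dir directory for the replayed run.
#' @return the replayed `camo_run`.
#' @export
replay_run <- function(run_dir, out_dir) {
  s <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                           simplifyVector = TRUE)
  cfg <- run_config(
    population_size = s$population_size, group_size = s$group_size,
    n_groups = s$n_groups, n_generations = s$n_generations,
    mutation_rate = s$mutation_rate, mutation_sd = s$mutation_sd,
    selection = s$selection,
    min_attacked_per_group = s$min_attacked_per_group, seed = s$seed
  )
  bspec <- background_spec(
    size = s$background$size, mean_lab = s$background$mean_lab,
    texture_scale = s$background$texture_scale,
    texture_contrast = s$background$texture_contrast,
    furrow_amplitude = s$background$furrow_amplitude,
    furrow_wavelength = s$background$furrow_wavelength,
    seed = s$background$seed
  )
  obs <- observer_model(weights = unlist(s$observer$weights),
                        tau = s$observer$tau,
                        max_attacks = s$observer$max_attacks)
  run_closed_loop(cfg, bspec, obs, out_dir = out_dir,
                  colour_space = s$colour_space,
                  target_px = s$target_px,
                  metrics_which = s$metrics_which)
}

#' Per-metric trend report across generations
#'
#' A lightweight stand-in for full statistical modelling of metric
#' trajectories: for each metric, the ordinary-least-squares slope of the
#' generation mean against generation index, a pairs-bootstrap confidence
#' interval, and a direction flag (`"decreasing"` / `"increasing"` if the
#' CI excludes zero, `"none"` otherwise).
#'
#' @param metrics data.frame with a `generation` column and one column
#'   per metric (per-target rows, as produced by [run_closed_loop()]).
#' @param metrics_which metric columns to report (default: all numeric
#'   columns except `generation`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed bootstrap seed.
#' @return data.frame: `metric`, `slope`, `ci_lo`, `ci_hi`, `direction`.
#' @export
trend_report <- function(metrics, metrics_which = NULL, n_boot = 1000,
                         level = 0.95, seed = 1L) {
  stopifnot("generation" %in% names(metrics))
  if (length(unique(metrics$generation)) < 3) {
    stop("trend report needs at least 3 generations")
  }
  if (is.null(metrics_which)) {
    metrics_which <- setdiff(
      names(metrics)[vapply(metrics, is.numeric, logical(1))],
      "generation")
  }
  alpha <- (1 - level) / 2
  bseeds <- derive_seeds(seed, length(metrics_which))
  rows <- lapply(seq_along(metrics_which), function(mi) {
    m <- metrics_which[mi]
    agg <- tapply(metrics[[m]], metrics$generation, mean)
    gen <- as.numeric(names(agg))
    y <- as.numeric(agg)
    slope <- ols_slope(gen, y)
    boots <- with_seed(bseeds[mi], {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(gen), replace = TRUE)
        if (length(unique(gen[idx])) < 2) return(NA_real_)
        ols_slope(gen[idx], y[idx])
      }, numeric(1))
    })
    ci <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    dir <- if (ci[1] > 0) "increasing" else if (ci[2] < 0) "decreasing" else "none"
    data.frame(metric = m, slope = slope, ci_lo = ci[1], ci_hi = ci[2],
               direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

ols_slope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}
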