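# The genetic algorithm: attack-order fitness ranks, survivor selection
# with the rescue rule, breeding, and the random-drift control mode.

#' Run configuration
#'
#' Holds the structural parameters of an evolution run. The default
#' mirrors the field protocol: 24 prey per population in six groups
#' (trays) of four, trials truncated once at least three prey per tray
#' have been attacked, survivors = the last two prey attacked per tray,
#' plus rescues.
#'
#' @param population_size total prey per generation (must equal
#'   `group_size * n_groups`).
#' @param group_size prey per tray.
#' @param n_groups trays per population.
#' @param n_generations number of scored generations.
#' @param box [colour_space_box()] the genomes decode into.
#' @param mutation_rate,mutation_sd GA operator parameters.
#' @param selection `"ranked"` or `"random-control"`.
#' @param min_attacked_per_group trial truncation point.
#' @param seed run seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(population_size = 24L, group_size = 4L,
                       n_groups = 6L, n_generations = 10L,
                       box = colour_space_box(), mutation_rate = 0.2,
                       mutation_sd = 0.1, selection = "ranked",
                       min_attacked_per_group = 3L, seed = 1L) {
  stopifnot(population_size == group_size * n_groups,
            group_size >= 2, n_groups >= 1,
            min_attacked_per_group >= 1,
            min_attacked_per_group <= group_size)
  selection <- match.arg(selection, c("ranked", "random-control"))
  structure(
    list(population_size = as.integer(population_size),
         group_size = as.integer(group_size),
         n_groups = as.integer(n_groups),
         n_generations = as.integer(n_generations),
         box = box, mutation_rate = mutation_rate,
         mutation_sd = mutation_sd, selection = selection,
         min_attacked_per_group = as.integer(min_attacked_per_group),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: %d prey (%d groups of %d), %d scored generations, %s selection\n",
    x$population_size, x$n_groups, x$group_size, x$n_generations,
    x$selection))
  invisible(x)
}

#' Create a population
#' @param genomes list of [camo_genome()].
#' @param generation generation index (>= 0).
#' @param provenance per-prey flag: "founder", "offspring", "rescued".
#' @return object of class `camo_population`.
#' @export
camo_population <- function(genomes, generation = 0L,
                            provenance = rep("founder", length(genomes))) {
  stopifnot(length(provenance) == length(genomes))
  ids <- vapply(genomes, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate prey ids in population")
  structure(list(generation = as.integer(generation), genomes = genomes,
                 provenance = provenance),
            class = "camo_population")
}

population_ids <- function(pop) {
  vapply(pop$genomes, function(g) g$id, character(1))
}

#' Founder population of uniform-gene genomes
#' @param cfg a [run_config()].
#' @param seed integer seed (default: `cfg$seed`).
#' @return generation-0 `camo_population`.
#' @export
founder_population <- function(cfg, seed = cfg$seed) {
  seeds <- derive_seeds(seed, cfg$population_size)
  genomes <- lapply(seq_len(cfg$population_size), function(i) {
    random_genome(seeds[i], id = sprintf("G000_%02d", i))
  })
  camo_population(genomes, generation = 0L)
}

# default grouping: prey i -> group ceiling(i / group_size), slot within
default_grouping <- function(pop, cfg) {
  ids <- population_ids(pop)
  data.frame(
    prey_id = ids,
    group = rep(seq_len(cfg$n_groups), each = cfg$group_size),
    slot = rep(seq_len(cfg$group_size), times = cfg$n_groups),
    stringsAsFactors = FALSE
  )
}

#' Fitness ranks from attack records
#'
#' Within each group, attacked prey are ranked by attack order (first
#' attacked = rank 1); unattacked prey share the remaining highest ranks
#' in a seeded-random order (the field protocol leaves at least one prey
#' unattacked, and no tie-break rule is prescribed). Rank `group_size` is
#' "the highest possible rank": the hardest prey to find.
#'
#' @param attacks data.frame with columns `prey_id`, `attack_index` (and
#'   optionally `group`); see [parse_attack_csv()].
#' @param grouping data.frame `prey_id`, `group`, `slot` covering the
#'   whole population.
#' @param cfg a [run_config()].
#' @param seed tie-break seed.
#' @return a `rank_table` data.frame: `prey_id`, `group`, `slot`,
#'   `attack_index` (NA if unattacked), `fitness_rank`.
#' @export
ranks_from_attacks <- function(attacks, grouping, cfg, seed = 1L) {
  stopifnot(all(c("prey_id", "attack_index") %in% names(attacks)))
  unknown <- setdiff(attacks$prey_id, grouping$prey_id)
  if (length(unknown)) {
    stop("unknown prey id(s) in attack records: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(attacks$prey_id)) {
    stop("duplicate attack record for prey ",
         attacks$prey_id[duplicated(attacks$prey_id)][1])
  }
  tab <- grouping
  tab$attack_index <- attacks$attack_index[match(tab$prey_id,
                                                 attacks$prey_id)]
  tab$fitness_rank <- NA_integer_
  gseeds <- derive_seeds(seed, max(tab$group))
  for (g in unique(tab$group)) {
    sel <- tab$group == g
    sub <- tab[sel, ]
    ai <- sub$attack_index
    if (anyDuplicated(ai[!is.na(ai)])) {
      stop(sprintf("duplicate attack_index in group %s", g))
    }
    rk <- rep(NA_integer_, nrow(sub))
    attacked <- which(!is.na(ai))
    rk[attacked[order(ai[attacked])]] <- seq_along(attacked)
    un <- which(is.na(ai))
    if (length(un)) {
      remaining <- setdiff(seq_len(nrow(sub)), rk[attacked])
      perm <- with_seed(gseeds[g],
                        remaining[sample.int(length(remaining))])
      rk[un] <- perm
    }
    tab$fitness_rank[sel] <- rk
  }
  class(tab) <- c("rank_table", "data.frame")
  tab
}

#' Survivor selection with the rescue rule
#'
#' Survivors are the last two prey attacked in each tray (fitness ranks
#' `group_size - 1` and `group_size`; ranks 3 and 4 in groups of four).
#' In addition, a prey ranked 1 or 2 in the current generation is rescued
#' if it held the highest possible rank (`group_size`) in the previous
#' generation: one unlucky early attack does not erase a previously
#' top-ranked pattern.
#'
#' Ranks are matched by prey id: a prey with no entry in the previous
#' table (e.g. a new offspring) can never be rescued.
#'
#' @param current current generation's `rank_table`.
#' @param previous previous generation's `rank_table`, or `NULL` for the
#'   first scored generation (no rescues possible).
#' @param cfg a [run_config()].
#' @return list: `survivors` (character ids), `rescues` (subset of
#'   survivors that were rescued).
#' @export
select_survivors <- function(current, previous = NULL, cfg) {
  gs <- cfg$group_size
  base <- current$prey_id[current$fitness_rank >= gs - 1L]
  rescues <- character()
  if (!is.null(previous)) {
    if (!any(current$prey_id %in% previous$prey_id)) {
      stop("current and previous rank tables cover different populations")
    }
    prev_rank <- previous$fitness_rank[match(current$prey_id,
                                             previous$prey_id)]
    rescues <- current$prey_id[current$fitness_rank %in% c(1L, 2L) &
                                 !is.na(prev_rank) & prev_rank == gs]
  }
  list(survivors = union(base, rescues), rescues = rescues)
}

#' Breed offspring from a survivor pool
#'
#' Produces `n` offspring (default: a full population). Each child draws
#' two distinct parents uniformly from the survivor pool (panmictic
#' across trays), applies uniform crossover, then mutation.
#'
#' @param survivors list of surviving `camo_genome`s (>= 2).
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @param generation index of the generation being created.
#' @param n number of offspring (default `cfg$population_size`).
#' @return a `camo_population` of offspring.
#' @export
breed_next_generation <- function(survivors, cfg, seed, generation,
                                  n = cfg$population_size) {
  if (length(survivors) < 2) stop("need at least 2 survivors to breed")
  seeds <- derive_seeds(seed, 3L * n)
  genomes <- lapply(seq_len(n), function(i) {
    pick <- with_seed(seeds[3 * i - 2], sample.int(length(survivors), 2))
    child <- crossover_genomes(survivors[[pick[1]]], survivors[[pick[2]]],
                               seed = seeds[3 * i - 1],
                               id = sprintf("G%03d_%02d", generation, i))
    mutate_genome(child, rate = cfg$mutation_rate,
                  magnitude = cfg$mutation_sd, seed = seeds[3 * i])
  })
  camo_population(genomes, generation = as.integer(generation),
                  provenance = rep("offspring", n))
}

#' Random-control survivor selection (neutral drift)
#'
#' Samples the same number of survivors per group as ranked selection
#' (two of four by default) uniformly at random, ignoring ranks. Control
#' runs isolate the GA's stochastic operators from observer selection.
#'
#' @param grouping data.frame `prey_id`, `group` for the population.
#' @param cfg a [run_config()].
#' @param seed integer seed.
#' @return character vector of survivor ids.
#' @export
random_control_selection <- function(grouping, cfg, seed) {
  gseeds <- derive_seeds(seed, max(grouping$group))
  unlist(lapply(unique(grouping$group), function(g) {
    ids <- grouping$prey_id[grouping$group == g]
    with_seed(gseeds[g], sample(ids, 2))
  }))
}

#' Generation record
#'
#' Bundles a generation's population with its rank table, survivor and
#' rescue sets, and the seed that produced it, so a run can be replayed
#' byte for byte.
#'
#' @param population a `camo_population`.
#' @param ranks its `rank_table` (NULL until scored).
#' @param survivors,rescues id vectors (empty until selection).
#' @param seed seed used to create this generation.
#' @return object of class `generation_record`.
#' @export
generation_record <- function(population, ranks = NULL,
                              survivors = character(),
                              rescues = character(), seed = NA_integer_) {
  ids <- population_ids(population)
  stopifnot(all(survivors %in% ids), all(rescues %in% survivors))
  structure(list(population = population, ranks = ranks,
                 survivors = survivors, rescues = rescues,
                 seed = as.integer(seed)),
            class = "generation_record")
}

#' Advance one generation
#'
#' Applies survivor selection (ranked, with the rescue rule, or random
#' control) to a scored generation record and assembles the next
#' population: the surviving patterns persist unchanged (they are
#' physically redeployed, which is what lets the rescue rule compare a
#' prey's ranks across consecutive generations), and offspring bred from
#' the survivor pool fill the remaining slots, keeping the population
#' size exact whatever the rescue count. Called once more after the last
#' scored generation, it produces the final unscored population that
#' accounts for the last set of observer decisions.
#'
#' @param record_n current (scored) `generation_record`.
#' @param record_prev previous `generation_record` or NULL.
#' @param cfg a [run_config()].
#' @param seed seed for selection + breeding.
#' @return a `generation_record` for generation N+1 (ranks NULL), with
#'   the parent record's survivor/rescue sets filled in by reference
#'   semantics: the updated parent record is attached as attribute
#'   `"scored"`.
#' @export
advance_generation <- function(record_n, record_prev = NULL, cfg, seed) {
  if (is.null(record_n$ranks)) stop("current record has no ranks")
  gen_next <- record_n$population$generation + 1L
  seeds <- derive_seeds(seed, 3L)
  if (cfg$selection == "random-control") {
    grouping <- default_grouping(record_n$population, cfg)
    surv_ids <- random_control_selection(grouping, cfg, seed = seeds[1])
    rescues <- character()
  } else {
    sel <- select_survivors(record_n$ranks,
                            if (!is.null(record_prev)) record_prev$ranks,
                            cfg)
    surv_ids <- sel$survivors
    rescues <- sel$rescues
  }
  ids <- population_ids(record_n$population)
  surv_ids <- ids[ids %in% surv_ids] # deterministic population order
  survivors <- record_n$population$genomes[match(surv_ids, ids)]
  n_off <- cfg$population_size - length(survivors)
  offspring <- if (n_off > 0) {
    breed_next_generation(survivors, cfg, seed = seeds[2],
                          generation = gen_next, n = n_off)$genomes
  } else {
    list()
  }
  prov <- c(ifelse(surv_ids %in% rescues, "rescued", "survivor"),
            rep("offspring", n_off))
  # mix carried survivors and offspring across trays
  perm <- with_seed(seeds[3], sample.int(cfg$population_size))
  nxt <- camo_population(c(survivors, offspring)[perm],
                         generation = gen_next, provenance = prov[perm])
  out <- generation_record(nxt, seed = seed)
  scored <- record_n
  scored$survivors <- surv_ids
  scored$rescues <- rescues
  attr(out, "scored") <- scored
  out
}
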