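# Study-shaped synthetic data: seeded gLV communities, noisy count
# tables on the 4-condition x 4-timepoint x 3-replicate sampling
# design, and feeding/reactor fixtures, so the whole pipeline is
# testable without any download.

#' Describe a study design
#'
#' Defaults emulate the four-reactor stress experiment: a control plus
#' three perturbed conditions, 16S samples at days 0, 56, 70 and 77,
#' three replicate sludge samples per timepoint, and a nanopore-scale
#' sequencing depth.
#'
#' @param conditions condition labels; the first is the unperturbed
#'   control.
#' @param sampling_days strictly increasing sampling days.
#' @param replicates replicate samples per (condition, day).
#' @param depth reads per sample for the multinomial draw.
#' @param n_taxa community size for the gLV ground truth.
#' @return List of class `study_design`.
#' @export
study_design <- function(conditions = c("control", "nalidixic", "GABA",
                                        "phosphate"),
                         sampling_days = c(0, 56, 70, 77),
                         replicates = 3, depth = 10000, n_taxa = 7) {
  stopifnot(length(conditions) >= 1, !anyDuplicated(conditions))
  if (any(diff(sampling_days) <= 0)) {
    abort("sampling_days must be strictly increasing",
          "digestor_domain_error")
  }
  check_number(replicates, "replicates", lower = 1)
  check_number(depth, "depth", lower = 1)
  check_number(n_taxa, "n_taxa", lower = 1)
  structure(list(conditions = conditions, sampling_days = sampling_days,
                 replicates = replicates, depth = depth, n_taxa = n_taxa),
            class = "study_design")
}

#' Describe a stressor perturbation
#'
#' A step change applied to the gLV parameters from `start_day` onward
#' (default day 42, the first stressor application): `delta_r` is added
#' to the growth rates and `delta_A` to the interaction matrix.
#'
#' @param delta_r scalar or length-n additive shift to r.
#' @param delta_A scalar (applied to all off-diagonal entries) or n x n
#'   additive shift to A.
#' @param start_day day from which the perturbed parameters apply.
#' @return List of class `perturbation_spec`.
#' @export
perturbation_spec <- function(delta_r = 0, delta_A = 0, start_day = 42) {
  check_number(start_day, "start_day", lower = 0)
  if (any(!is.finite(delta_r)) || any(!is.finite(unlist(delta_A)))) {
    abort("perturbation shifts must be finite", "digestor_domain_error")
  }
  structure(list(delta_r = delta_r, delta_A = delta_A,
                 start_day = start_day), class = "perturbation_spec")
}

apply_perturbation <- function(model, pert) {
  if (is.null(pert)) return(model)
  r <- model$r + pert$delta_r
  A <- model$A
  if (is.matrix(pert$delta_A)) {
    A <- A + pert$delta_A
  } else if (pert$delta_A != 0) {
    off <- row(A) != col(A)
    A[off] <- A[off] + pert$delta_A
  }
  glv_model(r, A, taxa = model$taxa)
}

#' Default stressor perturbations
#'
#' Uniform negative shifts to the off-diagonal interaction
#' coefficients, realising the observation that chemical stress pushes
#' the community toward a more competitive regime.  The antibiotic
#' condition gets the strongest shift (it had the deepest effect on
#' interaction patterns), the phosphate condition the mildest.
#'
#' @param conditions stressor condition labels (control excluded).
#' @param scale overall magnitude of the shifts (per abundance per day).
#' @param start_day first stressor application day.
#' @return Named list of [perturbation_spec()]s.
#' @export
default_perturbations <- function(conditions = c("nalidixic", "GABA",
                                                 "phosphate"),
                                  scale = 0.1, start_day = 42) {
  strength <- c(1, 0.7, 0.5)[seq_along(conditions)]
  out <- lapply(strength, function(s) {
    perturbation_spec(delta_r = 0, delta_A = -scale * s,
                      start_day = start_day)
  })
  stats::setNames(out, conditions)
}

# Lineages for the seven key fermentative/syntrophic digester genera
# that the modelling stage targets; used as default taxon labels.
.default_lineages <- c(
  "k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; f__Carnobacteriaceae; g__Trichococcus",
  "k__Bacteria; p__Bacteroidetes; c__Bacteroidia; o__Bacteroidales; f__Rikenellaceae; g__DMER64",
  "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Family XII; g__Sedimentibacter",
  "k__Bacteria; p__Cloacimonetes; c__Cloacimonadia; o__Cloacimonadales; f__Cloacimonadaceae; g__Candidatus Cloacimonas",
  "k__Bacteria; p__Proteobacteria; c__Deltaproteobacteria; o__Syntrophobacterales; f__Syntrophaceae; g__Smithella",
  "k__Bacteria; p__Cloacimonetes; c__Cloacimonadia; o__Cloacimonadales; f__Cloacimonadaceae; g__W5",
  "k__Bacteria; p__Chloroflexi; c__Anaerolineae; o__Anaerolineales; f__Anaerolineaceae; g__Longilinea")

default_taxa <- function(n) {
  base <- c("Trichococcus", "DMER64", "Sedimentibacter",
            "Cand_Cloacimonas", "Smithella", "W5", "Longilinea")
  if (n <= length(base)) {
    list(ids = base[seq_len(n)],
         taxonomy = parse_lineage(.default_lineages[seq_len(n)]))
  } else {
    ids <- c(base, sprintf("taxon_%02d", seq_len(n - length(base))))
    extra <- parse_lineage(rep(
      "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__; g__",
      n - length(base)))
    list(ids = ids,
         taxonomy = rbind(parse_lineage(.default_lineages), extra))
  }
}

#' Draw a random persistent gLV model
#'
#' Self-interactions are drawn negative but weak (gentle
#' self-limitation); growth rates are positive; off-diagonal
#' coefficients are drawn per unordered *pair*: with probability
#' `sparsity` the pair is non-interacting (both zero), otherwise the
#' two directions get independent half-normal magnitudes of scale
#' `interaction_scale` and *opposite* signs.  Antagonistic pairing plus
#' weak self-limitation yields sustained oscillatory dynamics -- the
#' predator-prey/syntrophic-loop regime in which interactions remain
#' identifiable from a single community time series; strongly
#' self-limited communities relax onto a low-dimensional manifold where
#' gradient matching cannot separate the coefficients.  The candidate
#' is accepted only if a community started from random positive
#' abundances persists (all abundances stay above the floor, none
#' diverge) over `horizon` days; otherwise off-diagonals are shrunk by
#' 30% and the check retried, up to `max_retries` times.
#'
#' @param n_taxa community size.
#' @param sparsity probability that an off-diagonal pair is
#'   non-interacting.
#' @param interaction_scale scale of the half-normal off-diagonal
#'   magnitudes.
#' @param seed RNG seed (fully reproducible draws).
#' @param horizon persistence-check horizon in days (default 77, the
#'   experiment length).
#' @param floor persistence floor.
#' @param max_retries shrink-and-retry budget.
#' @return A [glv_model()].
#' @export
sample_glv_model <- function(n_taxa, sparsity = 0.3,
                             interaction_scale = 0.4, seed = 1,
                             horizon = 77, floor = 1e-8,
                             max_retries = 20) {
  check_number(n_taxa, "n_taxa", lower = 1)
  check_number(sparsity, "sparsity", lower = 0, upper = 1)
  with_seed(seed, {
    r <- stats::runif(n_taxa, 0.3, 1)
    A <- matrix(0, n_taxa, n_taxa)
    if (n_taxa > 1) {
      for (i in seq_len(n_taxa - 1)) {
        for (j in (i + 1):n_taxa) {
          if (stats::runif(1) < sparsity) next
          s <- sample(c(-1, 1), 1)
          A[i, j] <- s * abs(stats::rnorm(1, 0, interaction_scale))
          A[j, i] <- -s * abs(stats::rnorm(1, 0, interaction_scale))
        }
      }
    }
    diag(A) <- -stats::runif(n_taxa, 0.15, 0.4)
    x0 <- stats::runif(n_taxa, 0.5, 1.5)
    off <- row(A) != col(A)
    td <- default_taxa(n_taxa)
    for (try in seq_len(max_retries)) {
      mdl <- glv_model(r, A, taxa = td$ids)
      ok <- tryCatch({
        traj <- glv_simulate(mdl, x0,
                             seq(0, horizon, length.out = 40),
                             floor = floor)
        min(traj$X) > floor && max(traj$X) < 1e6
      }, digestor_blowup_error = function(e) FALSE)
      if (ok) return(mdl)
      A[off] <- A[off] * 0.7
    }
    abort(paste0("no persistent community found in ", max_retries,
                 " retries; try a smaller interaction_scale"),
          "digestor_generation_error")
  })
}

#' Interior equilibrium of a gLV model
#'
#' Solves `A x = -r`; returns `NULL` when the solve fails or the
#' equilibrium is not strictly positive.
#'
#' @param model a [glv_model()].
#' @return Positive equilibrium vector or `NULL`.
#' @export
glv_equilibrium <- function(model) {
  x <- tryCatch(solve(model$A, -model$r), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x)) || any(x <= 0)) return(NULL)
  stats::setNames(as.numeric(x), model$taxa)
}

#' Generate a synthetic count table on a study design
#'
#' Per condition the gLV trajectory is simulated (with that condition's
#' [perturbation_spec()], if any) and evaluated at the sampling days.
#' For each replicate the true abundances are multiplied by lognormal
#' noise with coefficient of variation `noise_cv` (unit mean), closed
#' to proportions, and counts drawn from a multinomial at `depth`
#' reads.  The true model(s) and noise-free proportions are attached as
#' the `truth` attribute.
#'
#' @param model a [glv_model()] ground truth.
#' @param design a [study_design()].
#' @param x0 initial abundances; default the model's interior
#'   equilibrium when one exists, else all-ones.
#' @param perturbations named list of [perturbation_spec()]s keyed by
#'   condition (conditions without an entry run the base model).
#' @param noise_cv lognormal observation-noise coefficient of
#'   variation (default 0.05).
#' @param seed RNG seed.
#' @return An [abundance_table()] with `truth` attribute.
#' @export
generate_counts <- function(model, design = study_design(), x0 = NULL,
                            perturbations = NULL, noise_cv = 0.05,
                            seed = 1) {
  stopifnot(inherits(model, "glv_model"), inherits(design, "study_design"))
  check_number(noise_cv, "noise_cv", lower = 0)
  x0 <- x0 %||% glv_equilibrium(model) %||% rep(1, model$n)
  days <- design$sampling_days
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    counts <- NULL; meta <- NULL
    true_props <- list()
    for (cond in design$conditions) {
      pert <- perturbations[[cond]]
      sim_times <- sort(unique(c(days, if (!is.null(pert))
        pert$start_day)))
      traj <- simulate_with_perturbation(model, x0, sim_times, pert)
      Xd <- traj$X[match(days, sim_times), , drop = FALSE]
      P <- Xd / rowSums(Xd)
      rownames(P) <- paste0("day", days)
      true_props[[cond]] <- P
      for (di in seq_along(days)) {
        for (rep_i in seq_len(design$replicates)) {
          w <- P[di, ] * stats::rlnorm(model$n, -sdlog^2 / 2, sdlog)
          w <- w / sum(w)
          cnt <- stats::rmultinom(1, design$depth, w)[, 1]
          counts <- rbind(counts, cnt)
          meta <- rbind(meta, data.frame(
            sample_id = sprintf("%s_d%02d_r%d", cond, days[di], rep_i),
            condition = cond, day = days[di], replicate = rep_i))
        }
      }
    }
    rownames(counts) <- meta$sample_id
    colnames(counts) <- model$taxa
    td <- default_taxa(model$n)
    taxonomy <- if (identical(td$ids, model$taxa)) td$taxonomy
    tab <- abundance_table(counts, samples = meta, taxonomy = taxonomy)
    attr(tab, "truth") <- list(
      model = model, x0 = x0, proportions = true_props,
      perturbations = perturbations, noise_cv = noise_cv, seed = seed,
      design = design)
    tab
  })
}

#' Default feeding schedule of the stress experiment
#'
#' One unfed start-up week, then glucose three times a week (days 0, 2
#' and 4 of each week): 1 g/L during weeks 2-3 and 3 g/L from week 4
#' on.  From week 7 the stressor is added once a week in escalating
#' amounts -- 0.01, 0.1, 1, 10, 10 g/L for the organic stressors
#' (21.11 g/L in total) and 0.5, 5, 5, 5, 5 g/L for inorganic
#' phosphate (20.5 g/L in total).
#'
#' @param condition one of `"control"`, `"nalidixic"`, `"GABA"`,
#'   `"phosphate"`.
#' @return `data.frame` of feeding events (see [feeding_event()]).
#' @export
default_schedule <- function(condition = "control") {
  organic <- condition %in% c("nalidixic", "GABA")
  stressor_amounts <- if (condition == "control") numeric(5)
  else if (organic) c(0.01, 0.1, 1, 10, 10)
  else c(0.5, 5, 5, 5, 5)
  events <- list()
  for (week in 2:11) {
    glucose <- if (week <= 3) 1 else 3
    for (offset in c(0, 2, 4)) {
      day <- (week - 1) * 7 + offset
      stressor <- if (week >= 7 && offset == 0)
        stressor_amounts[week - 6] else 0
      events[[length(events) + 1]] <-
        feeding_event(day, substrate_load = glucose,
                      stressor_load = stressor,
                      stressor_is_organic = organic && stressor > 0)
    }
  }
  do.call(rbind, events)
}

#' Generate a complete synthetic study on disk
#'
#' Writes everything the pipeline consumes: a combined OTU count table
#' (TSV), sample metadata (TSV), the ground-truth model and
#' proportions (JSON), and per-condition feeding schedules plus the
#' reactor configuration (YAML).
#'
#' @param out_dir output directory (created if needed).
#' @param design a [study_design()].
#' @param perturbations named list of [perturbation_spec()]s; default
#'   [default_perturbations()] for the non-control conditions.
#' @param noise_cv observation-noise CV.
#' @param seed RNG seed; sub-seeds for model and counts are derived
#'   from it.
#' @param sparsity,interaction_scale passed to [sample_glv_model()].
#' @return Invisibly, a named list of the written paths plus the
#'   [abundance_table()].
#' @export
generate_study <- function(out_dir, design = study_design(),
                           perturbations = NULL, noise_cv = 0.05,
                           seed = 1, sparsity = 0.3,
                           interaction_scale = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(perturbations)) {
    perturbations <- default_perturbations(
      setdiff(design$conditions, design$conditions[1]))
  }
  model <- sample_glv_model(design$n_taxa, sparsity = sparsity,
                            interaction_scale = interaction_scale,
                            seed = seed)
  tab <- generate_counts(model, design, perturbations = perturbations,
                         noise_cv = noise_cv, seed = seed + 1)
  truth <- attr(tab, "truth")
  paths <- list(
    otu_table = file.path(out_dir, "otu_table.tsv"),
    metadata = file.path(out_dir, "sample_metadata.tsv"),
    truth = file.path(out_dir, "ground_truth.json"),
    schedule = file.path(out_dir, "feeding_schedule.yaml"))
  write_otu_table(tab, paths$otu_table)
  utils::write.table(tab$samples, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(taxa = model$taxa, r = unname(model$r),
         A = apply(unname(model$A), 1L, identity, simplify = FALSE),
         x0 = unname(truth$x0),
         proportions = lapply(truth$proportions, function(p)
           as.data.frame(p)),
         noise_cv = noise_cv, seed = seed,
         perturbations = lapply(perturbations, unclass)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  schedules <- lapply(design$conditions, function(cond) {
    df <- default_schedule(cond)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  })
  names(schedules) <- design$conditions
  yaml::write_yaml(list(
    reactor = list(working_volume = 3, exchange_volume = 0.15,
                   feedings_per_week = 3),
    conditions = schedules), paths$schedule)
  invisible(c(paths, list(table = tab, model = model)))
}

#' Read a feeding schedule written by [generate_study()]
#'
#' @param path YAML path.
#' @return List with `reactor` (a [reactor_config()]) and `conditions`
#'   (named list of feeding-event `data.frame`s).
#' @export
read_schedule <- function(path) {
  obj <- yaml::read_yaml(path)
  reactor <- do.call(reactor_config, obj$reactor)
  conditions <- lapply(obj$conditions, function(evs) {
    do.call(rbind, lapply(evs, function(e) do.call(feeding_event, e)))
  })
  list(reactor = reactor, conditions = conditions)
}
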