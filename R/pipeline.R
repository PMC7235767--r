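# Orchestration: wire chemistry, profiling, differential and gLV stages
# into one reproducible run with a manifest.

#' Validate a pipeline run configuration
#'
#' A run config is a plain list (typically read from YAML):
#' `inputs` (paths: `otu_table`, `metadata`, `schedule`, optional
#' `da_dir`), `stages` (subset of chem/profile/diff/glv), `params`
#' (`alpha`, `ridge`, `epsilon`, `top_n`, `seed`) and `out_dir`.
#' Referenced input paths must exist.
#'
#' @param config list or path to a YAML file.
#' @return The normalised config (invisibly usable by
#'   [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$stages <- config$stages %||% c("chem", "profile", "diff", "glv")
  bad <- setdiff(config$stages, c("chem", "profile", "diff", "glv"))
  if (length(bad)) {
    abort(paste0("unknown stages: ", paste(bad, collapse = ", ")),
          "digestor_config_error")
  }
  p <- config$params %||% list()
  p$alpha <- p$alpha %||% 0.05
  p$ridge <- p$ridge %||% 1e-3
  p$epsilon <- p$epsilon %||% 0
  p$top_n <- p$top_n %||% 10
  p$seed <- p$seed %||% 1
  check_number(p$alpha, "alpha", lower = 0, upper = 1)
  check_number(p$ridge, "ridge", lower = 0)
  check_number(p$epsilon, "epsilon", lower = 0)
  check_number(p$top_n, "top_n", lower = 1)
  config$params <- p
  if (is.null(config$out_dir)) {
    abort("config must name an out_dir", "digestor_config_error")
  }
  for (nm in names(config$inputs %||% list())) {
    path <- config$inputs[[nm]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("input '%s' does not exist: %s", nm, path),
            "digestor_config_error")
    }
  }
  config
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (chemistry and
#' profiling are independent; differential analysis and gLV inference
#' consume the profile stage's containers), writing per-stage TSV/JSON
#' outputs under `out_dir` and a JSON manifest recording package
#' version, seed, parameters and per-stage status.  A stage failure is
#' recorded in the manifest (status `"failed"`) and later stages that
#' depend on it are skipped; the attached `exit_code` attribute is 0
#' when everything ran, 2 otherwise.  Re-running with an identical
#' config reproduces identical outputs.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return The manifest (list), invisibly, with attribute `exit_code`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  manifest <- list(
    package = "digestor",
    version = as.character(utils::packageVersion("digestor")),
    seed = p$seed, params = p, stages = list())
  status <- function(name, st, msg = NULL, outputs = NULL) {
    manifest$stages[[name]] <<- list(status = st, message = msg,
                                     outputs = outputs)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, outputs = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    if (res$ok) status(name, "ok", outputs = res$outputs)
    else status(name, "failed", msg = res$msg)
    res$ok
  }

  tab <- NULL
  if (any(c("profile", "diff", "glv") %in% config$stages)) {
    meta <- if (!is.null(config$inputs$metadata))
      read_sample_metadata(config$inputs$metadata)
    tab <- read_otu_table(config$inputs$otu_table, samples = meta)
  }

  if ("chem" %in% config$stages) {
    run_stage("chem", function() {
      sch <- read_schedule(config$inputs$schedule)
      hrt <- hydraulic_retention_time(sch$reactor)
      olr <- do.call(rbind, lapply(names(sch$conditions), function(cn) {
        cbind(condition = cn, olr_by_week(sch$conditions[[cn]]))
      }))
      olr$olr_2dp <- round_half_up(olr$olr, 2)
      f_olr <- file.path(out_dir, "chem_olr_by_week.tsv")
      utils::write.table(olr, f_olr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f_sum <- file.path(out_dir, "chem_summary.json")
      jsonlite::write_json(list(
        retention_time_days = hrt,
        retention_time_2dp = trunc_digits(hrt, 2)),
        f_sum, auto_unbox = TRUE, digits = NA)
      c(f_olr, f_sum)
    })
  }

  profile <- NULL
  genus_tab <- NULL
  if ("profile" %in% config$stages) {
    run_stage("profile", function() {
      genus_tab <<- if ("genus" %in% names(tab$taxonomy))
        aggregate_rank(tab, "genus") else tab
      profile <<- relative_abundance(genus_tab)
      bc <- bray_curtis(profile)
      ord <- ordinate(bc, k = 2)
      f_bc <- file.path(out_dir, "profile_bray_curtis.tsv")
      utils::write.table(round(bc, 6), f_bc, sep = "\t", quote = FALSE)
      f_ord <- file.path(out_dir, "profile_pcoa.tsv")
      utils::write.table(
        data.frame(sample_id = rownames(ord$points),
                   axis1 = ord$points[, 1], axis2 = ord$points[, 2]),
        f_ord, sep = "\t", quote = FALSE, row.names = FALSE)
      f_top <- file.path(out_dir, "profile_top_taxa.tsv")
      tt <- top_taxa(profile, min(p$top_n, ncol(profile$proportions)))
      utils::write.table(
        data.frame(taxon = as.character(tt), score = attr(tt, "scores")),
        f_top, sep = "\t", quote = FALSE, row.names = FALSE)
      c(f_bc, f_ord, f_top)
    })
  }

  conds <- if (!is.null(tab)) unique(tab$samples$condition)
  control <- conds[1]
  stressors <- setdiff(conds, control)

  if ("diff" %in% config$stages) {
    if (is.null(profile)) {
      status("diff", "skipped", msg = "profile stage did not run")
    } else {
      run_stage("diff", function() {
        days <- setdiff(unique(tab$samples$day),
                        min(tab$samples$day))
        outs <- character()
        for (d in days) {
          shifts <- lapply(stressors, function(cn) {
            res <- fallback_da_test(genus_tab, cn, control, d)
            significant_shifts(res, alpha = p$alpha)
          })
          names(shifts) <- stressors
          vs <- venn_classify(shifts)
          f <- file.path(out_dir, sprintf("diff_venn_day%02d.json", d))
          jsonlite::write_json(
            list(day = d, total = vs$total,
                 counts = vs$counts, assignments = vs$assignments),
            f, auto_unbox = TRUE, digits = NA)
          outs <- c(outs, f)
        }
        outs
      })
    }
  }

  if ("glv" %in% config$stages) {
    if (is.null(profile)) {
      status("glv", "skipped", msg = "profile stage did not run")
    } else {
      run_stage("glv", function() {
        per_cond <- lapply(conds, function(cn) {
          keep <- genus_tab$samples$condition == cn
          abundance_table(genus_tab$counts[keep, , drop = FALSE],
                          samples = genus_tab$samples[keep, , drop = FALSE],
                          taxonomy = genus_tab$taxonomy)
        })
        names(per_cond) <- conds
        profs <- lapply(per_cond, relative_abundance)
        taxa <- intersect_top(profs, n = min(p$top_n,
                                             ncol(genus_tab$counts)))
        signs <- list()
        for (cn in conds) {
          pr <- profs[[cn]]
          days <- sort(unique(pr$samples$day))
          # replicate-averaged proportions per day, modelled taxa only
          Xd <- t(vapply(days, function(d) {
            colMeans(pr$proportions[pr$samples$day == d, taxa,
                                    drop = FALSE])
          }, numeric(length(taxa))))
          traj <- glv_trajectory(days, Xd, taxa = taxa)
          fit <- glv_infer(traj, ridge = p$ridge)
          signs[[cn]] <- classify_signs(fit$model, epsilon = p$epsilon)
        }
        counts <- lapply(conds, function(cn) {
          s <- count_interactions(signs[[cn]], label = cn)
          list(condition = cn, positive = s$positive,
               negative = s$negative, neutral = s$neutral)
        })
        shared <- lapply(stressors, function(cn) {
          list(condition = cn,
               shared_with_control = shared_interactions(signs[[control]],
                                                         signs[[cn]]))
        })
        uniq <- lapply(conds, function(cn) {
          list(condition = cn,
               unique = unique_interactions(
                 signs[[cn]], signs[setdiff(conds, cn)]))
        })
        f_sum <- file.path(out_dir, "glv_interactions.json")
        jsonlite::write_json(
          list(taxa = taxa, counts = counts, shared = shared,
               unique = uniq), f_sum, auto_unbox = TRUE, digits = NA)
        f_signs <- file.path(out_dir, "glv_sign_matrices.tsv")
        sm <- do.call(rbind, lapply(conds, function(cn) {
          s <- signs[[cn]]
          data.frame(condition = cn,
                     taxon_i = rep(rownames(s), times = ncol(s)),
                     taxon_j = rep(colnames(s), each = nrow(s)),
                     sign = as.vector(unclass(s)))
        }))
        utils::write.table(sm, f_signs, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        c(f_sum, f_signs)
      })
    }
  }

  statuses <- vapply(manifest$stages, `[[`, character(1), "status")
  exit_code <- if (any(statuses == "failed")) 2L else 0L
  manifest$ok <- exit_code == 0L
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  attr(manifest, "exit_code") <- exit_code
  invisible(manifest)
}
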