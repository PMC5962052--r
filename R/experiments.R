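# Pre-built staged protocols: each of the model's in-silico experiments as
# a one-call recipe.

.recipe_names <- c("interphase_setA", "interphase_setB", "tubulin_scan",
                   "nucleation_off", "dilution_10x", "prophase_switch",
                   "prophase_switch_5x_nucleation", "prophase_keep_kc",
                   "prophase_keep_kr", "param_swap", "zones_scan",
                   "noise_boundary")

#' List the available experiment recipes
#'
#' @return character vector of recipe names accepted by [recipe()].
#' @export
mt_recipes <- function() .recipe_names

.swap_one <- function(from, to, param) {
  di <- di_preset(from)
  other <- di_preset(to)
  for (f in paste0(param, c("_mean", "_sd"))) di[[f]] <- other[[f]]
  class(di) <- "di_params"
  di
}

#' Build a named experiment recipe
#'
#' Returns the fully parameterized stage lists for one of the model's
#' canonical experiments. Multi-condition experiments (`tubulin_scan`,
#' `param_swap`, `zones_scan`, `noise_boundary`) contain one stage list per
#' condition.
#'
#' Recipes:
#' \describe{
#'   \item{interphase_setA / interphase_setB}{single 10,000 s assembly at
#'     35 uM total tubulin.}
#'   \item{tubulin_scan}{assemblies at 20, 25, 30, 35 uM for each of Set A
#'     and Set B.}
#'   \item{nucleation_off}{assembly, then nucleation rate set to 0
#'     (default second-stage duration 173,000 s for Set A, 80,000 s for
#'     Set B).}
#'   \item{dilution_10x}{assembly, then the tubulin budget diluted 10-fold.}
#'   \item{prophase_switch}{Set A assembly, then prophase (NEBD)
#'     parameters for 1,000 s with nucleation unchanged;
#'     `prophase_switch_5x_nucleation` raises the per-site nucleation rate
#'     5-fold in the prophase stage.}
#'   \item{prophase_keep_kc / prophase_keep_kr}{prophase switch with the
#'     catastrophe (or rescue) frequency held at its interphase Set A
#'     value.}
#'   \item{param_swap}{the 8 runs swapping exactly one of v_g, v_s, k_c,
#'     k_r between Sets A and B, in both directions.}
#'   \item{zones_scan}{Set B with a 16-fold-stabilized interior and
#'     peripheral dynamic zone widths from 25 down to 1.25 um.}
#'   \item{noise_boundary}{Set B baseline, per-step dynamics noise only,
#'     0-3 um boundary jitter only, and both combined.}
#' }
#'
#' @param name recipe name (see [mt_recipes()]).
#' @param preset `"setA"` or `"setB"` where the experiment is defined for
#'   either interphase set (`nucleation_off`, `dilution_10x`).
#' @param replicates replicate count (default 4).
#' @param stage2_duration override for the second-stage duration, s.
#' @return an object of class `mt_recipe` with elements `name`,
#'   `conditions` (named list of stage lists) and `replicates`.
#' @examples
#' recipe("prophase_switch")
#' @export
recipe <- function(name, preset = c("setA", "setB"), replicates = 4,
                   stage2_duration = NULL) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% .recipe_names)
    stop("unknown recipe; valid names: ",
         paste(.recipe_names, collapse = ", "))
  preset <- match.arg(preset)
  no_nuc <- nucleation_spec(rate_per_site = 0)
  assembly <- function(set, total = NULL)
    stage_spec(10000, di_preset(set), total_tubulin = total)

  conditions <- switch(
    name,
    interphase_setA = list(setA = list(assembly("setA"))),
    interphase_setB = list(setB = list(assembly("setB"))),
    tubulin_scan = {
      grid <- expand.grid(set = c("setA", "setB"),
                          tub = c(20, 25, 30, 35),
                          stringsAsFactors = FALSE)
      conds <- lapply(seq_len(nrow(grid)), function(i)
        list(assembly(grid$set[i], grid$tub[i])))
      names(conds) <- sprintf("%s_%guM", grid$set, grid$tub)
      conds
    },
    nucleation_off = {
      dur <- if (!is.null(stage2_duration)) stage2_duration
      else if (preset == "setA") 173000 else 80000
      conds <- list(list(assembly(preset),
                         stage_spec(dur, di_preset(preset),
                                    nucleation = no_nuc)))
      names(conds) <- preset
      conds
    },
    dilution_10x = {
      dur <- if (!is.null(stage2_duration)) stage2_duration else 2000
      conds <- list(list(assembly(preset),
                         stage_spec(dur, di_preset(preset),
                                    dilution_factor = 0.1)))
      names(conds) <- preset
      conds
    },
    prophase_switch = list(nebd = list(
      assembly("setA"),
      stage_spec(if (is.null(stage2_duration)) 1000 else stage2_duration,
                 di_preset("nebd")))),
    prophase_switch_5x_nucleation = list(nebd_5x = list(
      assembly("setA"),
      stage_spec(if (is.null(stage2_duration)) 1000 else stage2_duration,
                 di_preset("nebd"),
                 nucleation = nucleation_spec(rate_per_site = 5 * 0.0005)))),
    prophase_keep_kc = list(keep_kc = list(
      assembly("setA"),
      stage_spec(if (is.null(stage2_duration)) 1000 else stage2_duration,
                 .swap_one("nebd", "setA", "k_c")))),
    prophase_keep_kr = list(keep_kr = list(
      assembly("setA"),
      stage_spec(if (is.null(stage2_duration)) 1000 else stage2_duration,
                 .swap_one("nebd", "setA", "k_r")))),
    param_swap = {
      grid <- expand.grid(from = c("setA", "setB"),
                          param = c("v_g", "v_s", "k_c", "k_r"),
                          stringsAsFactors = FALSE)
      conds <- lapply(seq_len(nrow(grid)), function(i) {
        to <- if (grid$from[i] == "setA") "setB" else "setA"
        list(stage_spec(10000, .swap_one(grid$from[i], to, grid$param[i])))
      })
      names(conds) <- sprintf("%s_swap_%s", grid$from, grid$param)
      conds
    },
    zones_scan = {
      widths <- c(25, 12.5, 6.25, 3.75, 2.5, 1.25)
      conds <- lapply(widths, function(w)
        list(stage_spec(10000, di_preset("setB"),
                        zones = zone_spec(peripheral_width = w))))
      names(conds) <- sprintf("width_%g", widths)
      conds
    },
    noise_boundary = list(
      baseline = list(assembly("setB")),
      dynamics_noise = list(
        stage_spec(10000, di_preset("setB"),
                   noise = noise_spec(vary_v_s = TRUE, vary_k_c = TRUE,
                                      vary_k_r = TRUE))),
      boundary_jitter = list(
        stage_spec(10000, di_preset("setB"),
                   noise = noise_spec(radius_jitter_max = 3))),
      both = list(
        stage_spec(10000, di_preset("setB"),
                   noise = noise_spec(vary_v_s = TRUE, vary_k_c = TRUE,
                                      vary_k_r = TRUE,
                                      radius_jitter_max = 3)))))

  structure(list(name = name, conditions = conditions,
                 replicates = as.integer(replicates)),
            class = "mt_recipe")
}

#' @export
print.mt_recipe <- function(x, ...) {
  cat(sprintf("Experiment recipe '%s': %d condition%s, %d replicate%s\n",
              x$name, length(x$conditions),
              if (length(x$conditions) > 1) "s" else "",
              x$replicates, if (x$replicates > 1) "s" else ""))
  for (nm in names(x$conditions)) {
    stg <- x$conditions[[nm]]
    cat(sprintf("  %-16s %d stage%s (%s s)\n", nm, length(stg),
                if (length(stg) > 1) "s" else "",
                paste(vapply(stg, function(s) s$duration, integer(1)),
                      collapse = " + ")))
  }
  invisible(x)
}

#' Run all conditions and replicates of a recipe
#'
#' Executes every condition of the recipe with `replicates` distinct,
#' recorded seeds, summarizes the steady-state window of each condition,
#' and (for staged recipes) computes the midpoint-crossing half-times of MT
#' count and mean length in the final stage.
#'
#' Replicate seeds are `seed + (condition index - 1) * 1000 + (replicate
#' index - 1)`, so any single run can be reproduced independently.
#'
#' @param recipe an [recipe()] object.
#' @param kinetics a [kinetic_constants()] object.
#' @param geometry a [cell_geometry()] object.
#' @param seed base integer seed.
#' @param replicates optional override of the recipe's replicate count.
#' @param dt step duration, s (default 1).
#' @param window steady-state averaging window, s, relative to the end of
#'   the first stage (default the last 2000 s of stage 1).
#' @return an object of class `mt_experiment`: per-condition lists of
#'   trajectories, seeds, steady-state summaries and (where defined)
#'   half-times.
#' @examples
#' \donttest{
#' ex <- run_experiment(recipe("interphase_setB"), seed = 1)
#' ex$summaries$setB
#' }
#' @export
run_experiment <- function(recipe, kinetics = kinetic_constants(),
                           geometry = cell_geometry(), seed = 1,
                           replicates = NULL, dt = 1, window = NULL) {
  stopifnot(inherits(recipe, "mt_recipe"))
  reps <- if (is.null(replicates)) recipe$replicates else as.integer(replicates)
  trajectories <- list()
  seeds <- list()
  summaries <- list()
  half_times <- list()
  for (ci in seq_along(recipe$conditions)) {
    nm <- names(recipe$conditions)[ci]
    stages <- recipe$conditions[[ci]]
    cond_seeds <- seed + (ci - 1L) * 1000L + seq_len(reps) - 1L
    trajs <- lapply(cond_seeds, function(s)
      simulate_mt_array(stages, kinetics, geometry, seed = s, dt = dt))
    t1_end <- stages[[1]]$duration
    w <- if (is.null(window)) c(max(0, t1_end - 2000), t1_end) else window
    summaries[[nm]] <- steady_state_summary(trajs, window = w)
    if (length(stages) > 1) {
      ht <- vapply(trajs, function(tr) {
        sel <- tr$time >= t1_end
        c(n_mt = half_time(tr$n_mt[sel], tr$time[sel] - t1_end),
          mean_length = half_time(tr$mean_length[sel],
                                  tr$time[sel] - t1_end))
      }, numeric(2))
      half_times[[nm]] <- rowMeans(ht, na.rm = TRUE)
    }
    trajectories[[nm]] <- trajs
    seeds[[nm]] <- cond_seeds
  }
  structure(list(name = recipe$name, trajectories = trajectories,
                 seeds = seeds, summaries = summaries,
                 half_times = half_times, replicates = reps),
            class = "mt_experiment")
}

#' @export
print.mt_experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s' (%d replicates per condition)\n",
              x$name, x$replicates))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-16s n_mt %.1f +/- %.1f | length %.2f +/- %.2f um | free %.2f +/- %.2f uM\n",
                nm, s$mean[1], s$sd[1], s$mean[2], s$sd[2],
                s$mean[3], s$sd[3]))
    if (!is.null(x$half_times[[nm]]))
      cat(sprintf("  %-16s half-times: n_mt %.0f s, mean length %.0f s\n",
                  "", x$half_times[[nm]]["n_mt"],
                  x$half_times[[nm]]["mean_length"]))
  }
  invisible(x)
}
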