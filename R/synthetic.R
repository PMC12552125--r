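# Synthetic Lipidyzer/SLA-style lipidome generator. The templates encode the
# qualitative cell-type orderings reported for iPS cell-derived brain cells
# (e.g. astrocyte-max CE, microglia-max SM/TG/FFA, neuron-max CER/LPC/LPE);
# the absolute fractions and species rosters are synthetic parameters, not
# measurements. See the methods vignette for the full noise model.

# Fatty-acyl building blocks for molecular-species rosters (carbons, db).
.fa_pool <- function(n) {
  fas <- rbind(
    c(12, 0), c(14, 0), c(14, 1), c(16, 0), c(16, 1), c(18, 0), c(18, 1),
    c(18, 2), c(18, 3), c(20, 1), c(20, 4), c(20, 5), c(22, 4), c(22, 6))
  fas[seq_len(min(n, nrow(fas))), , drop = FALSE]
}

# All multisets of k FAs from a pool of n -> matrix of (carbons, db) sums
# plus the chain list for naming.
.fa_combos <- function(n, k) {
  fas <- .fa_pool(n)
  idx <- utils::combn(nrow(fas) + k - 1L, k)
  idx <- idx - (seq_len(k) - 1L)  # combinations with repetition
  lapply(seq_len(ncol(idx)), function(j) fas[idx[, j], , drop = FALSE])
}

.roster_molecular <- function(class, n_fas, k) {
  combos <- .fa_combos(n_fas, k)
  names <- vapply(combos, function(ch) {
    ch <- ch[order(ch[, 1], ch[, 2]), , drop = FALSE]
    paste0(class, " ", paste(sprintf("%d:%d", ch[, 1], ch[, 2]),
                             collapse = "_"))
  }, character(1))
  data.frame(species = names,
             carbons = vapply(combos, function(ch) sum(ch[, 1]), numeric(1)),
             db = vapply(combos, function(ch) sum(ch[, 2]), numeric(1)),
             stringsAsFactors = FALSE)
}

.roster_sum <- function(class, carbons, dbs, db_cap = Inf) {
  g <- expand.grid(carbons = carbons, db = dbs)
  g <- g[g$db <= pmin(db_cap, g$carbons %/% 3), , drop = FALSE]
  data.frame(species = sprintf("%s %d:%d", class, g$carbons, g$db),
             carbons = g$carbons, db = g$db, stringsAsFactors = FALSE)
}

# Unimodal within-class weights over (carbons, db): a few dominant species
# and a long tail, as in real panels.
.class_weights <- function(roster, c0, d0, sc = 4, sd_ = 1.5) {
  w <- exp(-((roster$carbons - c0) / sc)^2 - ((roster$db - d0) / sd_)^2)
  w / sum(w)
}

.default_rosters <- function() {
  list(
    PC  = .roster_molecular("PC", 14, 2),
    PE  = .roster_molecular("PE", 14, 2),
    PS  = .roster_molecular("PS", 12, 2),
    PI  = .roster_molecular("PI", 12, 2),
    PG  = .roster_molecular("PG", 11, 2),
    DG  = .roster_molecular("DG", 12, 2),
    TG  = .roster_molecular("TG", 12, 3),
    LPC = .roster_sum("LPC", seq(14, 24, 2), 0:4),
    LPE = .roster_sum("LPE", seq(14, 24, 2), 0:4),
    SM  = .roster_sum("SM", seq(32, 44, 2), 0:3, db_cap = 3),
    CER = .roster_sum("CER", seq(14, 26, 2), 0:1, db_cap = 1),
    DCER = .roster_sum("DCER", seq(14, 26, 2), 0:1, db_cap = 1),
    HCER = .roster_sum("HCER", seq(14, 26, 2), 0:1, db_cap = 1),
    LCER = .roster_sum("LCER", seq(14, 26, 2), 0:1, db_cap = 1),
    CE  = .roster_sum("CE", seq(12, 22, 2), 0:6),
    FFA = .roster_sum("FFA", seq(12, 24, 2), 0:6)
  )
}

# Class-typical weight centers and spreads:
# (sum-composition carbons, double bonds, carbon sd, double-bond sd).
# TG gets a wide double-bond spread: real panels carry substantial mass in
# both saturated/monounsaturated (db <= 1) and polyunsaturated TGs.
.weight_centers <- list(
  PC = c(34, 2, 4, 1.8), PE = c(36, 3, 4, 1.8), PS = c(38, 3, 4, 1.8),
  PI = c(38, 4, 4, 1.8), PG = c(34, 2, 4, 1.8), DG = c(34, 2, 4, 2),
  TG = c(52, 2.5, 4, 2.5), LPC = c(18, 1, 4, 1.5), LPE = c(18, 1, 4, 1.5),
  SM = c(38, 1, 4, 1.5), CER = c(20, 0, 4, 1.5), DCER = c(20, 0, 4, 1.5),
  HCER = c(20, 0, 4, 1.5), LCER = c(20, 0, 4, 1.5), CE = c(18, 2, 4, 2),
  FFA = c(18, 1, 4, 2))

# Class fraction tables per cell type; PC absorbs the remainder so each
# column sums to exactly 1. Orderings follow the reported lipotypes.
.template_fractions <- function() {
  f <- rbind(
    PE   = c(0.200, 0.190, 0.180),
    SM   = c(0.020, 0.055, 0.110),
    CE   = c(0.030, 0.090, 0.020),
    CER  = c(0.040, 0.020, 0.015),
    DCER = c(0.006, 0.005, 0.004),
    HCER = c(0.010, 0.012, 0.015),
    LCER = c(0.006, 0.008, 0.010),
    DG   = c(0.012, 0.030, 0.020),
    TG   = c(0.050, 0.070, 0.120),
    FFA  = c(0.030, 0.040, 0.070),
    LPC  = c(0.030, 0.012, 0.010),
    LPE  = c(0.020, 0.008, 0.007),
    PG   = c(0.012, 0.012, 0.008),
    PI   = c(0.040, 0.040, 0.040),
    PS   = c(0.030, 0.055, 0.060))
  colnames(f) <- c("iNeuron", "iAstrocyte", "iMicroglia")
  rbind(f, PC = 1 - colSums(f))
}

#' Built-in cell-type lipotype templates
#'
#' Three synthetic templates — iNeuron, iAstrocyte, iMicroglia — over the
#' 16-class registry. Class fractions satisfy the reported qualitative
#' orderings (PC/PE dominant everywhere and highest in neurons; SM highest
#' in microglia, then astrocytes, then neurons; CE and DG highest in
#' astrocytes; CER, LPC and LPE highest in neurons; TG, FFA and PS highest
#' in microglia). Absolute values are free synthetic parameters.
#'
#' @param species_per_class Optional integer: deterministically thin each
#'   class roster to at most this many species, stratified over double-bond
#'   bins (so saturation tails survive) and renormalizing weights. Used to
#'   scale simulation studies down.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   species noise (default 0.2).
#' @param blank_level Expected blank background as a fraction of a species'
#'   typical biological signal (default 0.05).
#' @return Named list of `lipotype_template` objects. Each holds `fractions`
#'   (named class fractions summing to 1), `roster` (data.frame: species,
#'   class, carbons, db, weight — weights summing to 1 within each class),
#'   `noise_cv`, `blank_level`.
#' @export
make_templates <- function(species_per_class = NULL, noise_cv = 0.2,
                           blank_level = 0.05) {
  rosters <- .default_rosters()
  roster <- do.call(rbind, lapply(names(rosters), function(cl) {
    r <- rosters[[cl]]
    ctr <- .weight_centers[[cl]]
    r$class <- cl
    r$weight <- .class_weights(r, ctr[1], ctr[2], ctr[3], ctr[4])
    if (!is.null(species_per_class) && nrow(r) > species_per_class) {
      # thin stratified by double-bond bin so the saturation structure
      # (including db tails) survives; slots proportional to bin weight,
      # every occupied bin keeps at least one species
      binw <- tapply(r$weight, r$db, sum)
      slots <- stats::setNames(
        pmax(1L, as.integer(round(species_per_class * binw))), names(binw))
      while (sum(slots) > species_per_class) {
        i <- which(slots == max(slots))
        i <- i[which.min(binw[i])]  # shed the lightest of the fullest bins
        slots[i] <- slots[i] - 1L
      }
      keep <- unlist(lapply(names(binw), function(d) {
        idx <- which(r$db == as.integer(d))
        idx[order(-r$weight[idx])][seq_len(min(slots[d], length(idx)))]
      }))
      r <- r[sort(keep), , drop = FALSE]
      r$weight <- r$weight / sum(r$weight)
    }
    r
  }))
  rownames(roster) <- NULL
  fr <- .template_fractions()
  out <- lapply(colnames(fr), function(ct) {
    structure(list(name = ct,
                   fractions = stats::setNames(fr[, ct], rownames(fr)),
                   roster = roster, noise_cv = noise_cv,
                   blank_level = blank_level),
              class = "lipotype_template")
  })
  stats::setNames(out, colnames(fr))
}

#' @export
print.lipotype_template <- function(x, ...) {
  cat(sprintf(
    "<lipotype_template> %s: %d species, %d classes, noise_cv %.2f\n",
    x$name, nrow(x$roster), length(x$fractions), x$noise_cv))
  invisible(x)
}

#' Construct an effect specification
#'
#' An effect is a list of targets, each a species selector (a class, a class
#' plus a double-bond window, or an explicit species set) with a positive
#' multiplier, applied to one group of a simulated design.
#'
#' @param name Effect name.
#' @param targets List of lists with fields `multiplier` (positive) and one
#'   or more of `class` (character vector of codes), `db_min`, `db_max`
#'   (inclusive sum-composition double-bond window), `species` (explicit
#'   canonical names).
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(name, targets) {
  for (t in targets) {
    stopifnot(is.numeric(t$multiplier), is.finite(t$multiplier),
              t$multiplier > 0)
  }
  structure(list(name = name, targets = targets), class = "effect_spec")
}

#' Built-in effect specifications
#'
#' Three named effects mirroring the reported qualitative directions, with
#' synthetic default multipliers chosen to be detectable at n = 6 per arm:
#' * `apoe4` — all CE species up (x1.5), TG species with saturated/mono
#'   (db <= 1) or highly polyunsaturated (db > 5) sums up (x2), SM down
#'   (x0.7);
#' * `reactive` — CE down (x0.4), TG down (x0.5), saturated/monounsaturated
#'   (db <= 1) phospholipids up (x1.6), LCER up (x1.8) and HCER up (x1.6);
#' * `cholesterol_load` — CE up (x2.5).
#'
#' @return Named list of `effect_spec` objects.
#' @export
make_effects <- function() {
  list(
    apoe4 = effect_spec("apoe4", list(
      list(class = "CE", multiplier = 1.5),
      list(class = "TG", db_max = 1, multiplier = 2),
      list(class = "TG", db_min = 6, multiplier = 2),
      list(class = "SM", multiplier = 0.7))),
    reactive = effect_spec("reactive", list(
      list(class = "CE", multiplier = 0.4),
      list(class = "TG", multiplier = 0.5),
      list(class = phospholipid_classes(), db_max = 1, multiplier = 1.6),
      list(class = "LCER", multiplier = 1.8),
      list(class = "HCER", multiplier = 1.6))),
    cholesterol_load = effect_spec("cholesterol_load", list(
      list(class = "CE", multiplier = 2.5)))
  )
}

# Per-species multiplier vector implied by an effect spec (composable).
effect_multipliers <- function(effect, roster) {
  mult <- rep(1, nrow(roster))
  if (is.null(effect)) return(mult)
  stopifnot(inherits(effect, "effect_spec"))
  for (t in effect$targets) {
    sel <- rep(TRUE, nrow(roster))
    if (!is.null(t$class)) sel <- sel & roster$class %in% t$class
    if (!is.null(t$db_min)) sel <- sel & roster$db >= t$db_min
    if (!is.null(t$db_max)) sel <- sel & roster$db <= t$db_max
    if (!is.null(t$species)) sel <- sel & roster$species %in% t$species
    mult[sel] <- mult[sel] * t$multiplier
  }
  mult
}

#' Simulation design
#'
#' @param groups Character vector of group labels (>= 1).
#' @param n_per_group Biological samples per group (recycled).
#' @param n_experiments Independent experiments; wells are split across them
#'   as evenly as possible and `replicate_id` records the assignment.
#' @param n_blanks,n_qc Numbers of blank and QC samples (>= 2 blanks and
#'   >= 1 QC by default, as the ingest contract requires).
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(groups = c("control", "case"),
                              n_per_group = 6, n_experiments = 3,
                              n_blanks = 2, n_qc = 1) {
  if (length(groups) < 1L || any(n_per_group < 1L)) {
    lt_stop("design_error", "need >= 1 group with >= 1 sample each")
  }
  n_per_group <- rep_len(n_per_group, length(groups))
  if (n_experiments < 1L || n_experiments > min(n_per_group)) {
    lt_stop("design_error",
            "n_experiments must be in [1, min(n_per_group)]")
  }
  structure(list(groups = groups, n_per_group = n_per_group,
                 n_experiments = n_experiments, n_blanks = n_blanks,
                 n_qc = n_qc),
            class = "simulation_design")
}

#' Simulate a Lipidyzer/SLA-style dataset
#'
#' Concentration model per biological sample s and species i:
#' `conc = total_conc * fraction[class(i)] * weight[i] * multiplier[i, group(s)]
#' * exp(eps)`, with `eps ~ N(0, sigma^2)`, `sigma^2 = log(1 + noise_cv^2)`,
#' times a per-sample and a per-experiment global scale factor (which cancel
#' under percent-of-total normalization). Blanks are independent log-normals
#' centered at `blank_level` times each species' typical signal. To exercise
#' the blank filter, a configurable fraction of species is drawn near blank
#' level everywhere (`low_fraction`), and another fraction is near blank in
#' all groups except the last (`groupwise_fraction`, requires >= 2 groups) —
#' these are the species the reintroduction rule rescues.
#'
#' @param template A `lipotype_template` (see [make_templates()]).
#' @param design A `simulation_design`.
#' @param effects Named list mapping group label -> `effect_spec` (or NULL).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param total_conc Expected total lipid concentration (arbitrary units).
#' @param low_fraction Fraction of species drawn near blank level
#'   (default 0.05).
#' @param groupwise_fraction Fraction of species elevated only in the last
#'   group (default 0.02).
#' @param missing_rate Probability that a low-abundance measurement is
#'   reported missing (default 0.01).
#' @param sample_scale_cv,experiment_scale_cv,blank_cv CVs of the per-sample,
#'   per-experiment and blank log-normal scale factors.
#' @return A `lipidomics_dataset`; the generation manifest (seed, template
#'   name, effect names, noise parameters, exercised species) is attached as
#'   attribute `"manifest"`.
#' @export
simulate_dataset <- function(template, design = simulation_design(),
                             effects = NULL, seed,
                             total_conc = 500, low_fraction = 0.05,
                             groupwise_fraction = 0.02, missing_rate = 0.01,
                             sample_scale_cv = 0.1,
                             experiment_scale_cv = 0.1, blank_cv = 0.3) {
  stopifnot(inherits(template, "lipotype_template"),
            inherits(design, "simulation_design"))
  if (missing(seed)) lt_stop("design_error", "a seed is required")
  bad <- setdiff(names(effects), design$groups)
  if (length(bad)) {
    lt_stop("design_error", sprintf(
      "effects refer to unknown group(s): %s", paste(bad, collapse = ", ")))
  }
  set.seed(as.integer(seed))

  roster <- template$roster
  S <- nrow(roster)
  mu <- total_conc * template$fractions[roster$class] * roster$weight
  names(mu) <- roster$species

  # species exercising the filter paths
  n_low <- floor(low_fraction * S)
  n_grp <- if (length(design$groups) >= 2L) floor(groupwise_fraction * S)
           else 0L
  pick <- sample.int(S, n_low + n_grp)
  low_set <- pick[seq_len(n_low)]
  grp_set <- pick[setdiff(seq_len(n_low + n_grp), seq_len(n_low))]

  sigma <- sqrt(log(1 + template$noise_cv^2))
  sig_s <- sqrt(log(1 + sample_scale_cv^2))
  sig_e <- sqrt(log(1 + experiment_scale_cv^2))
  sig_b <- sqrt(log(1 + blank_cv^2))

  exp_scale <- exp(stats::rnorm(design$n_experiments, 0, sig_e))

  cols <- list(); meta <- list()
  for (gi in seq_along(design$groups)) {
    g <- design$groups[gi]
    mult <- effect_multipliers(effects[[g]], roster)
    mu_g <- mu * mult
    mu_g[low_set] <- mu_g[low_set] * template$blank_level
    if (gi < length(design$groups)) {
      mu_g[grp_set] <- mu_g[grp_set] * template$blank_level
    }
    expt <- rep_len(seq_len(design$n_experiments), design$n_per_group[gi])
    for (w in seq_len(design$n_per_group[gi])) {
      id <- sprintf("%s_e%d_w%d", g, expt[w], w)
      v <- mu_g * exp(stats::rnorm(S, 0, sigma)) *
        exp(stats::rnorm(1, 0, sig_s)) * exp_scale[expt[w]]
      if (missing_rate > 0) {
        lowish <- v < 3 * template$blank_level * mu
        v[lowish & stats::runif(S) < missing_rate] <- NA_real_
      }
      cols[[id]] <- v
      meta[[id]] <- data.frame(sample_id = id, sample_type = "sample",
                               replicate_id = sprintf("exp%d", expt[w]),
                               condition = g, stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(design$n_blanks)) {
    id <- sprintf("blank_%d", b)
    cols[[id]] <- template$blank_level * mu * exp(stats::rnorm(S, 0, sig_b))
    meta[[id]] <- data.frame(sample_id = id, sample_type = "blank",
                             replicate_id = NA_character_,
                             condition = NA_character_,
                             stringsAsFactors = FALSE)
  }
  for (q in seq_len(design$n_qc)) {
    id <- sprintf("qc_%d", q)
    cols[[id]] <- mu * exp(stats::rnorm(S, 0, sigma / 2))
    meta[[id]] <- data.frame(sample_id = id, sample_type = "qc",
                             replicate_id = NA_character_,
                             condition = NA_character_,
                             stringsAsFactors = FALSE)
  }

  mat <- do.call(cbind, cols)
  rownames(mat) <- roster$species
  samples <- build_sample_annotations(do.call(rbind, meta),
                                      group_vars = "condition")
  ds <- lipidomics_dataset(mat, samples, unit = "a.u.")
  attr(ds, "manifest") <- list(
    generator = "lipotyper synthetic lipidome (not instrument data)",
    seed = as.integer(seed), template = template$name,
    groups = as.list(stats::setNames(design$n_per_group, design$groups)),
    effects = lapply(effects, `[[`, "name"),
    noise_cv = template$noise_cv, blank_level = template$blank_level,
    total_conc = total_conc,
    n_low_species = n_low, n_groupwise_species = n_grp)
  ds
}
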