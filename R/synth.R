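# Synthetic data generation: a labeled seed set with a continuous
# structure-activity relationship, a drug-like screening library with
# planted active analogs, and noisy 4PL concentration-response tables.
# Everything is generated from a small scaffold + substituent grammar so
# the whole pipeline runs offline and deterministically.

# Drug-like scaffolds with 1-3 substitution sites marked (R1)/(R2)/(R3).
# The statin-like beta-hydroxy lactone and the indole/pyrrole scaffolds are
# deliberately included so screening demos mirror a statin-like hit family.
.sar_scaffolds <- function() {
  # Substitution sites R1/R2 sit at least three ring bonds apart on every
  # scaffold, so a site's radius-3 attachment environment never overlaps
  # the other variable substituent: environment keys are a function of
  # (scaffold, site) alone, which keeps the built-in fragment library
  # dense around every seed.
  data.frame(
    name = c("benzene", "pyridine", "pyrimidine", "naphthalene",
             "quinoline", "indole", "phenylthiophene", "phenylfuran",
             "phenylpyrazole", "statin_lactone", "piperidine",
             "phenylmorpholine", "cyclohexane", "biphenyl", "benzanilide",
             "phenoxybenzene"),
    smiles = c(
      "c1c(R1)ccc(R2)c1",
      "c1c(R1)ccc(R2)n1",
      "c1(R2)cnc(R1)nc1",
      "c1c(R1)cc2cc(R2)ccc2c1",
      "c1c(R1)cc2cc(R2)ccc2n1",
      "c1c(R1)cc2cc(R2)[nH]c2c1",
      "c1c(R1)sc(c1)-c1ccc(R2)cc1",
      "c1c(R1)oc(c1)-c1ccc(R2)cc1",
      "c1c(R1)[nH]nc1-c1ccc(R2)cc1",
      "O=C1CC(O)C(R2)C(Cc2ccc(R1)cc2)O1",
      "N1(R1)CCC(R2)CC1",
      "O1C(R2)CN(CC1)c1ccc(R1)cc1",
      "C1(R2)CCC(R1)CC1",
      "c1cc(R1)ccc1-c1ccc(R2)cc1",
      "O=C(Nc1ccc(R1)cc1)c1ccc(R2)cc1",
      "c1cc(R1)ccc1Oc1ccc(R2)cc1"),
    intercept = c(-0.2, -0.1, -0.2, 0.3,
                  0.4, 0.7, 0.1, 0.0,
                  0.3, 0.9, -0.4,
                  -0.5, -0.3, 0.2, 0.1,
                  0.0),
    stringsAsFactors = FALSE
  )
}

.sar_substituents <- function() {
  # ring closures inside substituents use digit 9 so they can never pair
  # with a scaffold ring-closure digit when spliced in
  c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "CC(C)C", "CCO", "CO",
    "OC", "OCC", "CCOC", "COC", "N", "NC", "NCC", "N(C)C", "CN(C)C",
    "CCN", "CCNC", "F", "Cl", "Br", "O", "C(=O)O", "C(=O)OC", "CC(=O)O",
    "C(=O)N", "C(=O)NC", "C(=O)N(C)C", "C#N", "C(F)(F)F", "S(C)(=O)=O",
    "S(N)(=O)=O", "SC", "c9ccccc9", "Cc9ccccc9", "Oc9ccccc9",
    "c9ccc(C)cc9", "c9ccc(F)cc9", "c9ccc(Cl)cc9", "c9ccc(O)cc9",
    "c9ccc(OC)cc9", "Cc9ccc(F)cc9", "CC(O)C", "C=C", "C=CC", "CC#N",
    "OC(F)F", "NC(=O)C", "NC(=O)CC", "CCCO", "CCCN", "Cc9ccco9",
    "Cc9cccs9", "CC(C)O", "OCCO", "OCCN", "OCCOC", "CCl", "CCF",
    "CC(F)F", "COCC", "CN", "CNC", "CNCC", "C(=O)C", "CC(=O)C",
    "C(=O)CC", "OC(=O)C", "N(CC)CC", "CCCl", "OCc9ccccc9",
    "NCc9ccccc9", "CCc9ccccc9", "OCCCO", "NS(C)(=O)=O", "CS(C)(=O)=O",
    "C(O)C", "C(N)C")
}

# Fixed standardization constants and weight vector of the latent activity
# model (logistic link over the 7 properties plus a scaffold intercept).
# Constants are typical drug-like centers/spreads, fixed in code so the
# latent surface is identical across datasets and seeds.
.sar_act_center <- c(logp = 2.0, hbd = 1.5, hba = 4.0, mw = 350,
                     tpsa = 70, rot_bonds = 4.0, n_rings = 2.5)
.sar_act_scale <- c(logp = 1.5, hbd = 1.5, hba = 2.5, mw = 120,
                    tpsa = 40, rot_bonds = 2.5, n_rings = 1.2)
# Discrimination leans on polarity (logP, TPSA, HBD) rather than size, so
# the inactive class stays property-matched to the actives in bulk
# (decoy-like realism) and both classes remain equally editable.
.sar_act_weights <- c(logp = 0.9, hbd = -0.7, hba = 0.35, mw = 0.25,
                      tpsa = -0.8, rot_bonds = -0.2, n_rings = 0.5)
.sar_act_intercept <- -0.1
# logit temperature: flattens the link so a single structural edit moves
# the latent activity only slightly (the continuous-SAR premise)
.sar_act_temperature <- 3

#' Latent activity of molecules under the synthetic SAR model
#'
#' Smooth logistic function of the seven physicochemical properties plus a
#' per-scaffold intercept. Because properties change continuously under
#' small structural edits, so does the latent activity: the generator's
#' continuous-SAR premise (low activity-cliff probability) holds by
#' construction.
#'
#' @param props property data.frame from [compute_properties()].
#' @param scaffold_intercept numeric vector (recycled).
#' @return latent activity in (0, 1).
#' @export
sar_latent_activity <- function(props, scaffold_intercept = 0) {
  z <- sweep(sweep(as.matrix(props[, names(.sar_act_center)]), 2,
                   .sar_act_center, "-"), 2, .sar_act_scale, "/")
  plogis((drop(z %*% .sar_act_weights) + scaffold_intercept +
            .sar_act_intercept) / .sar_act_temperature)
}

#' Synthetic SAR generator configuration
#'
#' @param n_active,n_inactive requested class counts (defaults 68 and 37,
#'   the seed-set sizes of the motivating screen).
#' @param label_threshold latent activity above which a molecule is labeled
#'   active. Default 0.5.
#' @param margin seeds must sit at least this far from the threshold on
#'   the latent scale (default 0.15). Curated seed sets contain compounds
#'   whose activity calls are confident, and the margin is what keeps the
#'   activity-cliff rate of single-edit analogs low (the continuous-SAR
#'   regime the augmentation relies on).
#' @param flip_prob label-noise probability (must stay below 0.1, the
#'   continuous-SAR regime). Default 0.08, a typical error rate for
#'   curated bioactivity labels.
#' @param rng_seed integer seed.
#' @return list of class `sar_config`.
#' @export
sar_config <- function(n_active = 68L, n_inactive = 37L,
                       label_threshold = 0.5, margin = 0.15,
                       flip_prob = 0.08, rng_seed = 1L) {
  stopifnot(n_active >= 1, n_inactive >= 1, flip_prob < 0.1,
            margin >= 0, margin < 0.5)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 label_threshold = label_threshold, margin = margin,
                 flip_prob = flip_prob, rng_seed = as.integer(rng_seed)),
            class = "sar_config")
}

# Sample one recipe (scaffold index + one substituent per site); at least
# one site is always substituted so every molecule carries an editable
# acyclic bond.
.sample_recipe <- function(scaf) {
  subs <- .sar_substituents()
  n_sites <- lengths(regmatches(scaf$smiles,
                                gregexpr("\\(R[0-9]\\)", scaf$smiles)))
  i <- sample.int(nrow(scaf), 1)
  k <- n_sites[i]
  chosen <- ifelse(runif(k) < 0.9, sample(subs, k, replace = TRUE), "")
  if (all(chosen == "")) chosen[sample.int(k, 1)] <- sample(subs, 1)
  list(scaffold = i, subs = chosen)
}

.assemble_recipe <- function(recipe, scaf) {
  smi <- scaf$smiles[recipe$scaffold]
  for (j in seq_along(recipe$subs)) {
    rep <- if (nzchar(recipe$subs[j])) paste0("(", recipe$subs[j], ")") else ""
    smi <- sub(sprintf("(R%d)", j), rep, smi, fixed = TRUE)
  }
  smi
}

# Sample a batch of unique valid molecules; returns data.frame with
# smiles/scaffold plus the recipe list as an attribute.
.sample_molecules <- function(n_batch, scaf, exclude = character(0)) {
  recipes <- replicate(n_batch, .sample_recipe(scaf), simplify = FALSE)
  raw <- vapply(recipes, .assemble_recipe, character(1), scaf = scaf)
  can <- suppressWarnings(canonicalize_smiles(raw))
  keep <- !is.na(can) & !duplicated(can) & !(can %in% exclude)
  out <- data.frame(smiles = can[keep],
                    scaffold = vapply(recipes[keep], `[[`, 0L, "scaffold"),
                    stringsAsFactors = FALSE)
  attr(out, "recipes") <- recipes[keep]
  out
}

#' Generate a labeled seed dataset with a continuous SAR
#'
#' Molecules are assembled from drug-like scaffolds and substituents, their
#' latent activity computed with [sar_latent_activity()], and labels
#' assigned by thresholding with a small label-flip noise. Sampling
#' continues until the requested per-class counts are met.
#'
#' @param cfg a [sar_config()].
#' @return molecule records (provenance `"seed"`) with extra columns
#'   `latent` and `scaffold`; attribute `recipes` holds the generative
#'   recipe of each row (used for planting library analogs).
#' @export
generate_sar_dataset <- function(cfg = sar_config()) {
  scaf <- .sar_scaffolds()
  set.seed(cfg$rng_seed)
  need <- c(active = cfg$n_active, inactive = cfg$n_inactive)
  got <- list(active = NULL, inactive = NULL)
  recipes <- list(active = list(), inactive = list())
  seen <- character(0)
  for (iter in seq_len(60)) {
    batch <- .sample_molecules(2L * sum(need), scaf, exclude = seen)
    if (nrow(batch) == 0) next
    seen <- c(seen, batch$smiles)
    props <- compute_properties(batch$smiles)
    latent <- sar_latent_activity(props, scaf$intercept[batch$scaffold])
    conf <- abs(latent - cfg$label_threshold) >= cfg$margin
    lab <- as.integer(latent >= cfg$label_threshold)
    flip <- runif(nrow(batch)) < cfg$flip_prob
    lab[flip] <- 1L - lab[flip]
    batch$latent <- latent
    batch$label <- lab
    brec <- attr(batch, "recipes")
    # confidence filter: keep seeds whose latent clears the margin
    batch <- batch[conf, , drop = FALSE]
    brec <- brec[conf]
    for (cls in c("active", "inactive")) {
      want <- if (cls == "active") 1L else 0L
      sel <- which(batch$label == want)
      take <- head(sel, max(0L, need[[cls]] - NROW(got[[cls]])))
      got[[cls]] <- rbind(got[[cls]], batch[take, , drop = FALSE])
      recipes[[cls]] <- c(recipes[[cls]], brec[take])
    }
    if (NROW(got$active) >= need["active"] &&
        NROW(got$inactive) >= need["inactive"]) break
  }
  if (NROW(got$active) < need["active"] ||
      NROW(got$inactive) < need["inactive"])
    stop("infeasible class counts for the scaffold set / activity model")
  all <- rbind(got$active, got$inactive)
  rec <- molecule_records(all$smiles,
                          id = sprintf("seed_%03d", seq_len(nrow(all))),
                          label = all$label, provenance = "seed",
                          canonicalize = FALSE)
  rec$latent <- all$latent
  rec$scaffold <- scaf$name[all$scaffold]
  attr(rec, "recipes") <- c(recipes$active, recipes$inactive)
  rec
}

#' Generate an unlabeled screening library with planted active analogs
#'
#' Draws drug-like molecules from the scaffold grammar. When labeled seed
#' records from [generate_sar_dataset()] are supplied, a fraction of the
#' library consists of single-substituent analogs of active seeds
#' ("planted positives") providing retrieval ground truth.
#'
#' @param n library size (>= 10).
#' @param rng_seed integer seed.
#' @param seeds optional seed records carrying a `recipes` attribute.
#' @param planted_fraction fraction of `n` planted as active analogs
#'   (default 0.1; only used when `seeds` given).
#' @return molecule records (provenance `"library"`, label `NA`); attribute
#'   `planted` holds the ids of planted analogs.
#' @export
generate_screening_library <- function(n, rng_seed = 1L, seeds = NULL,
                                       planted_fraction = 0.1) {
  stopifnot(n >= 10)
  scaf <- .sar_scaffolds()
  subs <- .sar_substituents()
  set.seed(rng_seed)
  exclude <- if (!is.null(seeds)) seeds$smiles else character(0)

  planted <- character(0)
  if (!is.null(seeds)) {
    recipes <- attr(seeds, "recipes")
    act <- which(seeds$label == 1L)
    if (is.null(recipes) || !length(act)) {
      warning("seeds carry no recipes or no actives; nothing planted")
    } else {
      n_plant <- max(1L, round(planted_fraction * n))
      tries <- 0L
      while (length(planted) < n_plant && tries < 50L * n_plant) {
        tries <- tries + 1L
        r <- recipes[[sample(act, 1)]]
        j <- sample.int(length(r$subs), 1)
        r$subs[j] <- sample(subs, 1)
        can <- suppressWarnings(
          canonicalize_smiles(.assemble_recipe(r, scaf)))
        if (!is.na(can) && !(can %in% c(exclude, planted)))
          planted <- c(planted, can)
      }
    }
  }

  background <- character(0)
  while (length(background) < n - length(planted)) {
    b <- .sample_molecules(2L * n, scaf,
                           exclude = c(exclude, planted, background))
    background <- c(background,
                    head(b$smiles, n - length(planted) - length(background)))
  }
  smiles <- c(planted, background)
  ids <- sprintf("lib_%04d", seq_along(smiles))
  rec <- molecule_records(smiles, id = ids, label = NA_integer_,
                          provenance = "library", canonicalize = FALSE)
  # shuffle so planted molecules are not positionally identifiable
  ord <- sample.int(nrow(rec))
  planted_ids <- rec$id[seq_along(planted)]
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "planted") <- planted_ids
  rec
}

#' Built-in reference compound collection for fragment libraries
#'
#' A deterministic drug-like collection drawn from the scaffold grammar,
#' shipped so fragment-library construction needs no external download.
#'
#' @param n collection size (default 160).
#' @param rng_seed integer seed (default 7731).
#' @return molecule records (provenance `"library"`).
#' @export
reference_fragment_collection <- function(n = 300L, rng_seed = 7731L) {
  scaf <- .sar_scaffolds()
  set.seed(rng_seed)
  out <- character(0)
  while (length(out) < n) {
    b <- .sample_molecules(2L * n, scaf, exclude = out)
    out <- c(out, head(b$smiles, n - length(out)))
  }
  molecule_records(out, id = sprintf("ref_%04d", seq_len(n)),
                   provenance = "library", canonicalize = FALSE)
}

#' 4PL parameter set
#'
#' @param min_resp lower asymptote (% of negative control).
#' @param max_resp upper asymptote (% of negative control).
#' @param ic50 half-maximal concentration (uM).
#' @param hill Hill slope.
#' @return list of class `fourpl_params`.
#' @export
fourpl_params <- function(min_resp, max_resp, ic50, hill = 1) {
  stopifnot(ic50 > 0, max_resp >= min_resp)
  structure(list(min_resp = min_resp, max_resp = max_resp, ic50 = ic50,
                 hill = hill),
            class = "fourpl_params")
}

#' Evaluate the 4PL concentration-response equation
#'
#' `Y = Min + (Max - Min) / (1 + (X / IC50)^Hill)`: with Hill > 0 the
#' response falls from Max (low concentration) to Min (high
#' concentration), the inhibitor convention used throughout this package.
#' This is the standard inhibitor-versus-normalized-response form
#' `Min + (Max - Min) / (1 + (IC50 / X)^HillSlope)` with
#' `HillSlope = -Hill`; at `X = IC50` both give `(Min + Max) / 2`.
#'
#' @param x concentrations (uM).
#' @param p a [fourpl_params()].
#' @return responses (% of control).
#' @export
fourpl_response <- function(x, p) {
  p$min_resp + (p$max_resp - p$min_resp) / (1 + (x / p$ic50)^p$hill)
}

#' The 10-point assay concentration ladder (uM)
#' @export
assay_concentrations <- function() {
  c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 25, 50, 100)
}

#' Dose-response assay generator configuration
#'
#' @param params generating-truth [fourpl_params()].
#' @param concentrations ladder (default [assay_concentrations()]).
#' @param n_reps replicates per concentration (default 3).
#' @param noise_sd Gaussian noise SD in percentage points (default 5).
#' @param basal_rate negative-control enzymatic rate, umol/min/mg
#'   (default 1.2).
#' @param compound,form labels written into the table.
#' @param rng_seed integer seed.
#' @return list of class `assay_config`.
#' @export
assay_config <- function(params, concentrations = assay_concentrations(),
                         n_reps = 3L, noise_sd = 5, basal_rate = 1.2,
                         compound = "cmpd", form = "lactone",
                         rng_seed = 1L) {
  stopifnot(inherits(params, "fourpl_params"), n_reps >= 1, noise_sd >= 0,
            all(concentrations > 0))
  structure(list(params = params, concentrations = concentrations,
                 n_reps = as.integer(n_reps), noise_sd = noise_sd,
                 basal_rate = basal_rate, compound = compound, form = form,
                 rng_seed = as.integer(rng_seed)),
            class = "assay_config")
}

#' Generate a synthetic plate-style concentration-response table
#'
#' Emulates the assay design: `n_reps` wells at each ladder concentration
#' with responses drawn from the 4PL curve plus Gaussian noise (in
#' percentage points of control), and `n_reps` negative-control wells at
#' the basal rate (concentration 0).
#'
#' @param cfg an [assay_config()].
#' @return data.frame with columns `compound`, `form`, `concentration_uM`,
#'   `replicate`, `rate`, `control_flag`.
#' @export
generate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "assay_config"))
  set.seed(cfg$rng_seed)
  conc <- rep(cfg$concentrations, each = cfg$n_reps)
  repl <- rep(seq_len(cfg$n_reps), times = length(cfg$concentrations))
  pct <- fourpl_response(conc, cfg$params) +
    rnorm(length(conc), 0, cfg$noise_sd)
  treated <- data.frame(compound = cfg$compound, form = cfg$form,
                        concentration_uM = conc, replicate = repl,
                        rate = cfg$basal_rate * pct / 100,
                        control_flag = "treated",
                        stringsAsFactors = FALSE)
  ctrl_pct <- 100 + rnorm(cfg$n_reps, 0, cfg$noise_sd)
  controls <- data.frame(compound = cfg$compound, form = cfg$form,
                         concentration_uM = 0,
                         replicate = seq_len(cfg$n_reps),
                         rate = cfg$basal_rate * ctrl_pct / 100,
                         control_flag = "negative",
                         stringsAsFactors = FALSE)
  rbind(treated, controls)
}
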