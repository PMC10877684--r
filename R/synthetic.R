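# Seeded synthetic cohort generator.
#
# Repertoires are built so that every planted quantity is exactly
# recoverable from the emitted tables:
#  * productive read totals are identical in the PB and VAT repertoires of
#    an individual, so a clone's frequency comparison between compartments
#    equals its count comparison — planted expansion directions are exact,
#    never blurred by normalization;
#  * private CDR3 sequences are unique cohort-wide, so the public clones are
#    exactly the planted public pool;
#  * recirculating clones are drawn from VAT clones with count >= 2 so a
#    strictly smaller PB count always exists for VAT-expanded clones.

TRBV_GENES <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-5", "TRBV7-9", "TRBV9",
                "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV28", "TRBV30")
TRBJ_GENES <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-3",
                "TRBJ2-7")

#' Describe one cohort group for the synthetic generator
#'
#' @param group Group label (`"LC"`, `"OB-ND"`, `"OB-Dys"`).
#' @param n_individuals Number of individuals.
#' @param clones_per_repertoire Unique productive clones per repertoire.
#' @param zipf_exponent Exponent of the power-law clone-size distribution.
#' @param public_pool_size Number of cohort-wide public clones contributed
#'   by this scenario's groupings (pooled across scenarios at generation).
#' @param public_pool_rate Probability that an individual beyond the two
#'   guaranteed carriers also carries a given public clone.
#' @param recirc_fraction Fraction `f` of VAT clones also present in PB.
#' @param pb_expansion_bias Probability `d` that a recirculating clone is
#'   more expanded in PB than in VAT.
#' @param nonproductive_rate Fraction of emitted clonotype rows that are
#'   non-productive (stop-codon) spikes.
#' @param motif_spikes Optional list of `list(motif =, rate =)` entries: the
#'   motif is embedded in the central region of that fraction of VAT CDR3s.
#'   Spiked sequences emulate a specificity cluster: they share a V gene
#'   (optional `v_gene` field, default `"TRBV19"`) and a common CDR3 length
#'   (optional `length` field, default 14), mirroring the V-restriction and
#'   length bias of antigen-selected motif groups.
#' @param tie_rate Probability of planting an exactly tied recirculating
#'   clone (default 0: continuous-frequency regime, no ties).
#' @return A `group_scenario` list.
#' @export
group_scenario <- function(group, n_individuals, clones_per_repertoire = 500,
                           zipf_exponent = 1.1, public_pool_size = 0,
                           public_pool_rate = 0.3, recirc_fraction = 0.1,
                           pb_expansion_bias = 0.5, nonproductive_rate = 0.05,
                           motif_spikes = NULL, tie_rate = 0) {
  stopifnot(n_individuals >= 1, clones_per_repertoire >= 10,
            zipf_exponent > 0,
            recirc_fraction >= 0, recirc_fraction <= 1,
            pb_expansion_bias >= 0, pb_expansion_bias <= 1,
            nonproductive_rate >= 0, nonproductive_rate < 1,
            tie_rate >= 0, tie_rate <= 1)
  structure(list(group = match.arg(group, GROUPS),
                 n_individuals = n_individuals,
                 clones_per_repertoire = clones_per_repertoire,
                 zipf_exponent = zipf_exponent,
                 public_pool_size = public_pool_size,
                 public_pool_rate = public_pool_rate,
                 recirc_fraction = recirc_fraction,
                 pb_expansion_bias = pb_expansion_bias,
                 nonproductive_rate = nonproductive_rate,
                 motif_spikes = motif_spikes,
                 tie_rate = tie_rate),
            class = "group_scenario")
}

#' Default study-like scenarios
#'
#' Three groups mirroring the study structure: 4 lean controls with almost
#' all recirculating clones VAT-expanded, 6 obese normoglycemic with a VAT
#' majority, and 7 obese dysglycemic with higher recirculation and a PB
#' majority.
#'
#' @param clones_per_repertoire Unique productive clones per repertoire.
#' @param public_pool_size Cohort-wide planted public clones.
#' @return A list of three [group_scenario()] objects.
#' @export
default_scenarios <- function(clones_per_repertoire = 500,
                              public_pool_size = 30) {
  list(
    group_scenario("LC", 4, clones_per_repertoire,
                   public_pool_size = public_pool_size,
                   recirc_fraction = 0.05, pb_expansion_bias = 0.03),
    group_scenario("OB-ND", 6, clones_per_repertoire,
                   public_pool_size = public_pool_size,
                   recirc_fraction = 0.08, pb_expansion_bias = 0.23),
    group_scenario("OB-Dys", 7, clones_per_repertoire,
                   public_pool_size = public_pool_size,
                   recirc_fraction = 0.12, pb_expansion_bias = 0.58))
}

# Stateful unique CDR3 factory: "C" + core + "F", total length 12-18.
new_seq_factory <- function() {
  used <- new.env(parent = emptyenv())
  function(n = 1, motif = NULL, len = NULL) {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        L <- if (is.null(len)) sample(12:18, 1) else len
        core <- sample(AA20, L - 2, replace = TRUE)
        if (!is.null(motif)) {
          # place the motif fully inside the central region (positions
          # 4..L-3 of the full sequence = 3..L-4 of the core)
          km <- nchar(motif)
          lo <- 3
          hi <- (L - 4) - km + 1
          if (hi < lo) next
          at <- sample(lo:hi, 1)
          core[at:(at + km - 1)] <- strsplit(motif, "")[[1]]
        }
        s <- paste0("C", paste(core, collapse = ""), "F")
        if (is.null(used[[s]])) {
          used[[s]] <- TRUE
          out[i] <- s
          break
        }
      }
    }
    out
  }
}

zipf_counts <- function(n, exponent, reads_per_clone) {
  w <- (seq_len(n))^(-exponent)
  w <- sample(w)                     # random rank assignment
  extra <- n * (reads_per_clone - 1)
  as.integer(1 + stats::rmultinom(1, extra, w)[, 1])
}

#' Generate a synthetic paired-compartment cohort with ground truth
#'
#' For each individual of each scenario, draws a VAT repertoire with
#' power-law clone sizes and random CDR3s, copies a fraction
#' `recirc_fraction` of VAT clones into the PB repertoire with a planted
#' expansion direction (`PB` with probability `pb_expansion_bias`), injects
#' cohort-wide public clones, non-productive spikes, and optional motif
#' spikes, and generates consistent clinical records. Fully deterministic
#' given `seed`.
#'
#' @param scenarios List of [group_scenario()]; default [default_scenarios()].
#' @param seed Integer RNG seed.
#' @param subsets Cell subsets to emit (default both `"PD1pos"` and
#'   `"PD1neg"`).
#' @param reads_per_clone Mean reads per clone (sets sequencing depth).
#' @param dir Optional directory: when given, writes AIRR TSVs, a YAML
#'   manifest, a clinical CSV and a ground-truth JSON there.
#' @return A list of class `tcr_simulation`: `cohort` (a [cohort()]),
#'   `truth` (see Details), `scenarios`, `seed`.
#'
#' @details `truth` contains: `recirc` (tibble `individual_id`, `subset`,
#'   `cdr3_aa`, `direction`), `params` (per group: planted `f` and `d`),
#'   `public_pool` (planted public CDR3s), `public_carriers` (tibble),
#'   `spiked_motifs` (tibble `individual_id`, `subset`, `cdr3_aa`, `motif`),
#'   `nonproductive` (tibble of spiked rows), `vgene_probs`.
#' @export
generate_cohort <- function(scenarios = default_scenarios(), seed = 1,
                            subsets = SUBSETS, reads_per_clone = 10,
                            dir = NULL) {
  if (inherits(scenarios, "group_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "group_scenario")))
  set.seed(seed)
  next_seq <- new_seq_factory()

  # cohort-level V-gene usage (Dirichlet draw) shared by all repertoires
  vprobs <- stats::rgamma(length(TRBV_GENES), shape = 2)
  vprobs <- setNames(vprobs / sum(vprobs), TRBV_GENES)

  individuals <- purrr::map_dfr(scenarios, function(sc)
    tibble::tibble(group = sc$group,
                   individual_id = paste0(sub("OB-", "", sc$group), "_",
                                          seq_len(sc$n_individuals))))
  sc_by_group <- setNames(scenarios,
                          vapply(scenarios, `[[`, character(1), "group"))

  # public pool: every pool clone is planted in >=2 carriers spanning >=2
  # groups where possible, plus extra carriers at public_pool_rate
  pool_size <- max(vapply(scenarios, `[[`, numeric(1), "public_pool_size"))
  pool_rate <- max(vapply(scenarios, `[[`, numeric(1), "public_pool_rate"))
  public_pool <- character(0)
  carriers <- list()
  if (pool_size > 0 && nrow(individuals) >= 2) {
    public_pool <- next_seq(pool_size)
    n_groups <- dplyr::n_distinct(individuals$group)
    for (s in public_pool) {
      if (n_groups >= 2) {
        g2 <- sample(unique(individuals$group), 2)
        base <- vapply(g2, function(g)
          sample(individuals$individual_id[individuals$group == g], 1),
          character(1))
      } else {
        base <- sample(individuals$individual_id, 2)
      }
      rest <- setdiff(individuals$individual_id, base)
      extra <- rest[stats::runif(length(rest)) < pool_rate]
      carriers[[s]] <- c(base, extra)
    }
  }

  reps <- list()
  truth_recirc <- list()
  truth_spike <- list()
  truth_np <- list()

  for (ii in seq_len(nrow(individuals))) {
    id <- individuals$individual_id[[ii]]
    grp <- individuals$group[[ii]]
    sc <- sc_by_group[[grp]]
    n <- sc$clones_per_repertoire
    pool_here <- public_pool[vapply(carriers, function(cc) id %in% cc,
                                    logical(1))]
    if (length(pool_here) > n %/% 2) {
      pool_here <- pool_here[seq_len(n %/% 2)]
    }

    for (sub in subsets) {
      # --- VAT ---
      n_spike <- 0
      spike_seqs <- character(0)
      spike_motifs <- character(0)
      spike_v <- character(0)
      if (!is.null(sc$motif_spikes)) {
        for (ms in sc$motif_spikes) {
          k_ms <- max(0L, round(ms$rate * n))
          if (k_ms > 0) {
            sq <- next_seq(k_ms, motif = ms$motif,
                           len = ms$length %||% 14)
            spike_seqs <- c(spike_seqs, sq)
            spike_motifs <- c(spike_motifs, rep(ms$motif, k_ms))
            spike_v <- c(spike_v, rep(ms$v_gene %||% "TRBV19", k_ms))
          }
        }
        n_spike <- length(spike_seqs)
      }
      n_private <- n - length(pool_here) - n_spike
      if (n_private < 0) {
        rlang::abort("infeasible parameters: public pool + motif spikes exceed repertoire size",
                     class = "tcrtrack_value_error")
      }
      vat_seqs <- c(pool_here, spike_seqs, next_seq(n_private))
      vat_counts <- zipf_counts(n, sc$zipf_exponent, reads_per_clone)
      total_reads <- sum(vat_counts)

      # --- recirculating clones ---
      n_shared <- round(sc$recirc_fraction * n)
      eligible <- which(vat_counts >= 2)
      if (n_shared > length(eligible)) {
        rlang::abort("infeasible parameters: recirc_fraction exceeds expanded-clone supply",
                     class = "tcrtrack_value_error")
      }
      shared_idx <- if (n_shared > 0) sample(eligible, n_shared) else integer(0)
      u <- stats::runif(n_shared)
      direction <- ifelse(u < sc$tie_rate, "TIED",
                          ifelse(stats::runif(n_shared) < sc$pb_expansion_bias,
                                 "PB", "VAT"))
      shared_pb_counts <- integer(n_shared)
      for (j in seq_len(n_shared)) {
        cv <- vat_counts[shared_idx[j]]
        shared_pb_counts[j] <- switch(direction[j],
          # modest over-expansion keeps the PB read budget feasible even
          # when the Zipf head recirculates; only the direction is planted
          PB = cv + 1L + stats::rpois(1, ceiling(cv / 4)),
          VAT = sample.int(cv - 1L, 1),
          TIED = cv)
      }

      # --- PB: shared clones + private clones, same productive read total ---
      n_private_pb <- n - n_shared
      remaining <- total_reads - sum(shared_pb_counts)
      if (remaining < n_private_pb) {
        rlang::abort("infeasible parameters: shared-clone reads exhaust the PB repertoire",
                     class = "tcrtrack_value_error")
      }
      pb_private_seqs <- next_seq(n_private_pb)
      w <- sample((seq_len(n_private_pb))^(-sc$zipf_exponent))
      pb_private_counts <- as.integer(
        1 + stats::rmultinom(1, remaining - n_private_pb, w)[, 1])
      pb_seqs <- c(vat_seqs[shared_idx], pb_private_seqs)
      pb_counts <- c(shared_pb_counts, pb_private_counts)

      # --- non-productive spikes ---
      n_np <- round(sc$nonproductive_rate / (1 - sc$nonproductive_rate) * n)
      make_np <- function(m) {
        if (m == 0) return(tibble::tibble(cdr3_aa = character(),
                                          count = integer()))
        sq <- next_seq(m)
        pos <- vapply(sq, function(s) sample(4:(nchar(s) - 3), 1), integer(1))
        substr(sq, pos, pos) <- "*"
        tibble::tibble(cdr3_aa = sq, count = 1L + stats::rpois(m, 3))
      }
      np_vat <- make_np(n_np)
      np_pb <- make_np(n_np)

      build_rep <- function(seqs, counts, np, compartment,
                            v_override = NULL) {
        all_seqs <- c(seqs, np$cdr3_aa)
        m <- length(all_seqs)
        v <- sample(TRBV_GENES, m, replace = TRUE, prob = vprobs)
        if (!is.null(v_override)) {
          v[seq_along(v_override)][!is.na(v_override)] <-
            v_override[!is.na(v_override)]
        }
        repertoire(tibble::tibble(
          cdr3_aa = all_seqs,
          v_gene = v,
          j_gene = sample(TRBJ_GENES, m, replace = TRUE),
          count = c(counts, np$count),
          productive = c(rep(TRUE, length(seqs)),
                         rep(FALSE, nrow(np)))),
          id, grp, compartment, sub)
      }
      vat_v_override <- rep(NA_character_, n)
      if (n_spike > 0) {
        vat_v_override[length(pool_here) + seq_len(n_spike)] <- spike_v
      }
      reps[[length(reps) + 1]] <- build_rep(vat_seqs, vat_counts, np_vat,
                                            "VAT", vat_v_override)
      reps[[length(reps) + 1]] <- build_rep(pb_seqs, pb_counts, np_pb, "PB")

      if (n_shared > 0) {
        truth_recirc[[length(truth_recirc) + 1]] <- tibble::tibble(
          individual_id = id, group = grp, subset = sub,
          cdr3_aa = vat_seqs[shared_idx], direction = direction)
      }
      if (n_spike > 0) {
        truth_spike[[length(truth_spike) + 1]] <- tibble::tibble(
          individual_id = id, subset = sub, cdr3_aa = spike_seqs,
          motif = spike_motifs, v_gene = spike_v)
      }
      if (n_np > 0) {
        truth_np[[length(truth_np) + 1]] <- tibble::tibble(
          individual_id = id, subset = sub,
          cdr3_aa = c(np_vat$cdr3_aa, np_pb$cdr3_aa),
          compartment = rep(c("VAT", "PB"), c(nrow(np_vat), nrow(np_pb))))
      }
    }
  }

  clinical <- generate_clinical(individuals)
  sim <- structure(list(
    cohort = cohort(reps, clinical = clinical),
    truth = list(
      recirc = dplyr::bind_rows(truth_recirc),
      params = purrr::map_dfr(scenarios, function(sc)
        tibble::tibble(group = sc$group, f = sc$recirc_fraction,
                       d = sc$pb_expansion_bias)),
      public_pool = public_pool,
      public_carriers = if (length(carriers))
        tibble::tibble(cdr3_aa = rep(names(carriers),
                                     lengths(carriers)),
                       individual_id = unlist(carriers, use.names = FALSE))
        else tibble::tibble(cdr3_aa = character(),
                            individual_id = character()),
      spiked_motifs = dplyr::bind_rows(truth_spike),
      nonproductive = dplyr::bind_rows(truth_np),
      vgene_probs = vprobs),
    scenarios = scenarios,
    seed = seed),
    class = "tcr_simulation")
  if (!is.null(dir)) write_cohort(sim, dir)
  sim
}

# Clinical values drawn inside the defining range of each group so the ADA
# classification of every synthetic record matches its cohort group.
generate_clinical <- function(individuals) {
  n <- nrow(individuals)
  glucose <- numeric(n); insulin <- numeric(n)
  hba1c <- numeric(n); meds <- logical(n)
  for (i in seq_len(n)) {
    g <- individuals$group[[i]]
    if (g == "LC") {
      glucose[i] <- stats::runif(1, 78, 95)
      hba1c[i] <- stats::runif(1, 4.8, 5.5)
      insulin[i] <- stats::runif(1, 3, 8)
    } else if (g == "OB-ND") {
      glucose[i] <- stats::runif(1, 80, 99)
      hba1c[i] <- stats::runif(1, 4.9, 5.6)
      insulin[i] <- stats::runif(1, 8, 16)
    } else {
      diabetic <- stats::runif(1) < 0.5
      if (diabetic) {
        glucose[i] <- stats::runif(1, 126, 180)
        hba1c[i] <- stats::runif(1, 6.5, 8.5)
        meds[i] <- stats::runif(1) < 0.7
      } else {
        glucose[i] <- stats::runif(1, 100, 125)
        hba1c[i] <- stats::runif(1, 5.7, 6.4)
      }
      insulin[i] <- stats::runif(1, 12, 30)
    }
  }
  clinical_record(individuals$individual_id, round(glucose, 1),
                  round(insulin, 1), round(hba1c, 2), meds)
}

#' Write a simulated cohort to disk
#'
#' Emits one AIRR Rearrangement TSV per repertoire, a `manifest.yaml`
#' mapping files to sample metadata, a `clinical.csv`, and a
#' `ground_truth.json`.
#'
#' @param sim A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "tcr_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- list()
  for (r in sim$cohort$repertoires) {
    fname <- sprintf("%s_%s_%s.tsv", r$individual_id, r$compartment, r$subset)
    write_airr_table(r, file.path(dir, fname))
    samples[[length(samples) + 1]] <- list(
      file = fname, individual_id = r$individual_id, group = r$group,
      compartment = r$compartment, subset = r$subset, format = "airr")
  }
  clin <- sim$cohort$clinical
  readr::write_csv(clin[, c("individual_id", "glucose", "insulin", "hba1c",
                            "on_meds")],
                   file.path(dir, "clinical.csv"), progress = FALSE)
  yaml::write_yaml(list(seed = sim$seed, clinical = "clinical.csv",
                        samples = samples),
                   file.path(dir, "manifest.yaml"))
  truth <- sim$truth
  truth$vgene_probs <- as.list(truth$vgene_probs)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a synthetic VDJdb-style annotation database
#'
#' Plants exactly `n_matches` records hitting the given clones (score >= 1,
#' MHC class II, CD4) plus, for other clones, decoy records that each fail
#' one confidence filter (score 0, MHC class I, or CD8 compartment) and a
#' few records for CDR3s absent from the cohort.
#'
#' @param clones Character vector of CDR3 sequences to draw targets from.
#' @param n_matches Number of clones to plant a valid record for.
#' @param species Antigen species labels to sample from.
#' @param seed RNG seed.
#' @param n_decoys_per_filter Decoy records per failing filter dimension.
#' @return A list: `db` (annotation tibble, shuffled), `planted` (character
#'   vector of the CDR3s with a valid record).
#' @export
generate_annotation_db <- function(clones, n_matches,
                                   species = c("InfluenzaA", "CMV",
                                               "T.aestivum", "HIV-1"),
                                   seed = 1, n_decoys_per_filter = 3) {
  stopifnot(n_matches <= length(unique(clones)))
  set.seed(seed)
  clones <- unique(clones)
  planted <- if (n_matches > 0) sample(clones, n_matches) else character(0)
  rec <- function(cdr3, score, mhc, comp) {
    tibble::tibble(cdr3_aa = cdr3,
                   epitope = paste0("EPI", substr(cdr3, 2, 6)),
                   antigen_species = sample(species, length(cdr3),
                                            replace = TRUE),
                   mhc_class = mhc, compartment_label = comp, score = score)
  }
  db <- rec(planted, sample(1:3, n_matches, replace = TRUE), "MHCII", "CD4")
  rest <- setdiff(clones, planted)
  nd <- min(n_decoys_per_filter, length(rest))
  decoys <- list()
  if (nd > 0) {
    pick <- function() sample(rest, nd)
    decoys <- list(rec(pick(), 0L, "MHCII", "CD4"),        # score fails
                   rec(pick(), sample(1:3, nd, TRUE), "MHCI", "CD8"),
                   rec(pick(), sample(1:3, nd, TRUE), "MHCI", "CD4"),
                   rec(pick(), sample(1:3, nd, TRUE), "MHCII", "CD8"))
  }
  foreign <- rec(paste0("CZZZ", sprintf("%04d", seq_len(3)), "F"),
                 2L, "MHCII", "CD4")
  db <- dplyr::bind_rows(c(list(db), decoys, list(foreign)))
  db <- db[sample.int(nrow(db)), , drop = FALSE]
  list(db = db, planted = planted)
}

#' Generate a synthetic expression matrix with planted HOMA-IR correlates
#'
#' Planted genes are a scaled copy of the samples' HOMA-IR plus Gaussian
#' noise calibrated so the expected Pearson correlation is about
#' `r_target`; the remaining genes are independent noise, on a log2
#' RPKM-like scale.
#'
#' @param clinical Clinical tibble with `individual_id` and `homa_ir`.
#' @param n_genes Total genes.
#' @param n_correlated Number of planted correlated genes.
#' @param r_target Target correlation of planted genes.
#' @param seed RNG seed.
#' @return A list: `expr` (matrix genes x samples), `planted` (gene names).
#' @export
generate_expression <- function(clinical, n_genes = 500, n_correlated = 30,
                                r_target = 0.95, seed = 1) {
  stopifnot(n_correlated <= n_genes, nrow(clinical) >= 3,
            r_target > 0, r_target <= 1)
  set.seed(seed)
  n <- nrow(clinical)
  z <- as.numeric(scale(clinical$homa_ir))
  sigma <- if (r_target < 1) sqrt(1 / r_target^2 - 1) else 0
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  planted <- genes[seq_len(n_correlated)]
  expr <- matrix(stats::rnorm(n_genes * n, mean = 5, sd = 1),
                 nrow = n_genes, dimnames = list(genes,
                                                 clinical$individual_id))
  for (i in seq_len(n_correlated)) {
    expr[i, ] <- 5 + z + stats::rnorm(n, sd = sigma)
  }
  list(expr = expr, planted = planted)
}
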