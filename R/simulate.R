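#' Configure the synthetic atlas generator
#'
#' Builds the parameter set for [simulate_atlas()]. Defaults emulate a
#' desk-scale six-donor atlas: ~1260 left-cortical samples of which 60 fall
#' inside the affected mask (mirroring a 61-versus-1224 style design),
#' additive per-donor batch offsets, an exchangeable intra-donor residual
#' correlation, probes nested in genes with heterogeneous fidelity, Bernoulli
#' detection calls, RNA-seq companions for two donors, and cell-type marker
#' sets partially overlapping the planted genes.
#'
#' @param n_donors Number of donors.
#' @param samples_per_donor Samples per donor (all left-cortical).
#' @param n_genes Gene universe size.
#' @param probes_per_gene_distribution Named numeric vector of probabilities;
#'   names are probe counts (e.g. `c("1" = .3, "2" = .5, "3" = .2)`).
#' @param donor_batch_sd SD of additive per-donor, per-gene offsets
#'   (log-intensity units).
#' @param residual_sd Residual SD (log-intensity units).
#' @param intra_donor_correlation Exchangeable residual correlation within a
#'   donor, in `[0, 1)`.
#' @param n_planted_de Number of genes given a regional effect inside the mask.
#' @param de_effect_size Planted mean shift inside the mask, in units of
#'   `residual_sd`; signs alternate between planted genes.
#' @param mask_fraction Fraction of samples placed inside the affected mask.
#' @param detection_rate_range Length-2 probability range for probe-specific
#'   detection-call rates; the designated best probe of each gene receives the
#'   top of the range.
#' @param rnaseq_donors Number of leading donors with an RNA-seq companion.
#' @param rnaseq_noise_sd SD of independent RNA-seq measurement noise.
#' @param marker_set_specs Tibble with columns `set_name`, `set_size`,
#'   `n_overlap` (overlap with the planted gene set). The default plants three
#'   strongly overlapping marker sets, four disjoint ones, one at the
#'   five-gene inclusion boundary and two below it.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_donors = 6,
                              samples_per_donor = 210,
                              n_genes = 2000,
                              probes_per_gene_distribution =
                                c("1" = 0.3, "2" = 0.5, "3" = 0.2),
                              donor_batch_sd = 0.8,
                              residual_sd = 0.4,
                              intra_donor_correlation = 0.3,
                              n_planted_de = 50,
                              de_effect_size = 1.0,
                              mask_fraction = 60 / 1260,
                              detection_rate_range = c(0.3, 0.95),
                              rnaseq_donors = 2,
                              rnaseq_noise_sd = 0.2,
                              marker_set_specs = default_marker_specs(),
                              seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors),
              samples_per_donor = as.integer(samples_per_donor),
              n_genes = as.integer(n_genes),
              probes_per_gene_distribution = probes_per_gene_distribution,
              donor_batch_sd = donor_batch_sd,
              residual_sd = residual_sd,
              intra_donor_correlation = intra_donor_correlation,
              n_planted_de = as.integer(n_planted_de),
              de_effect_size = de_effect_size,
              mask_fraction = mask_fraction,
              detection_rate_range = detection_rate_range,
              rnaseq_donors = as.integer(rnaseq_donors),
              rnaseq_noise_sd = rnaseq_noise_sd,
              marker_set_specs = as_tibble(marker_set_specs),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

default_marker_specs <- function() {
  tibble(set_name = c("CellType_A", "CellType_B", "CellType_C",
                      "CellType_D", "CellType_E", "CellType_F", "CellType_G",
                      "CellType_edge", "CellType_tiny3", "CellType_tiny4"),
         set_size = c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 5L, 3L, 4L),
         n_overlap = c(8L, 8L, 7L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
}

validate_simulation_config <- function(cfg) {
  counts <- c(cfg$n_donors, cfg$samples_per_donor, cfg$n_genes)
  if (any(counts < 1)) stop_imagetx("all counts must be positive")
  if (cfg$n_planted_de < 0 || cfg$n_planted_de > cfg$n_genes) {
    stop_imagetx("n_planted_de must lie in [0, n_genes]")
  }
  if (cfg$intra_donor_correlation < 0 || cfg$intra_donor_correlation >= 1) {
    stop_imagetx("intra_donor_correlation must lie in [0, 1)")
  }
  if (cfg$mask_fraction <= 0 || cfg$mask_fraction >= 1) {
    stop_imagetx("mask_fraction must lie in (0, 1)")
  }
  pr <- cfg$detection_rate_range
  if (length(pr) != 2 || any(pr < 0) || any(pr > 1) || pr[1] > pr[2]) {
    stop_imagetx("detection_rate_range must be probabilities (low, high)")
  }
  p <- cfg$probes_per_gene_distribution
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop_imagetx("probes_per_gene_distribution must be named probabilities summing to 1")
  }
  if (cfg$rnaseq_donors < 1 || cfg$rnaseq_donors > cfg$n_donors) {
    stop_imagetx("rnaseq_donors must lie in [1, n_donors]")
  }
  specs <- cfg$marker_set_specs
  if (!all(c("set_name", "set_size", "n_overlap") %in% names(specs))) {
    stop_imagetx("marker_set_specs needs set_name, set_size, n_overlap")
  }
  if (any(specs$n_overlap > specs$set_size) ||
      any(specs$n_overlap > cfg$n_planted_de)) {
    stop_imagetx("marker overlap cannot exceed set size or planted-gene count")
  }
  invisible(cfg)
}

# Mask geometry shared by the generator: a 40 x 48 x 40 grid with 2 mm
# isotropic spacing centred on the midline; world x negative = left.
sim_affine <- function() {
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- c(-39, -47, -39)
  aff
}

# 0-based voxel index box of the left-hemisphere mask
sim_box_vox <- list(i = 6:13, j = 20:27, k = 18:25)

sim_mask_pair <- function() {
  grid <- array(0, dim = c(40, 48, 40))
  b <- sim_box_vox
  grid[b$i + 1, b$j + 1, b$k + 1] <- 1
  left <- mask_volume(grid, sim_affine(), name = "mask_left")
  gridr <- array(0, dim = c(40, 48, 40))
  # mirrored twin: world x -> -x, so voxel i -> 39 - i
  gridr[(39 - b$i) + 1, b$j + 1, b$k + 1] <- 1
  right <- mask_volume(gridr, sim_affine(), name = "mask_right")
  list(left = left, right = right)
}

# world-space boxes: voxel centres of the 1-block, shrunk/expanded so that
# interpolated values are exactly 1 inside and exactly 0 outside
sim_world_box <- function(margin) {
  b <- sim_box_vox
  aff <- sim_affine()
  lo <- aff %*% c(min(b$i), min(b$j), min(b$k), 1)
  hi <- aff %*% c(max(b$i), max(b$j), max(b$k), 1)
  list(lo = lo[1:3] - margin, hi = hi[1:3] + margin)
}

#' Generate a synthetic atlas with planted ground truth
#'
#' Simulates the complete input surface of the pipeline: per-donor probe
#' annotation, expression, detection calls and sample coordinates; an
#' affected-region mask (plus its mirrored right-hemisphere twin); RNA-seq
#' companions; marker gene sets; and the ground truth needed to score every
#' downstream stage.
#'
#' Gene-level expression follows
#' `baseline + donor offset + inside-mask effect + correlated residual`,
#' with the residual exchangeably correlated within donor. Probe-level values
#' add probe-specific bias and noise; the designated best probe per gene has
#' the lowest noise and the highest detection rate. Exactly
#' `round(mask_fraction * n)` samples are placed inside the mask (at least one
#' voxel clear of its boundary, so trilinear membership is unambiguous).
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, per-donor CSV bundles, the two
#'   NIfTI masks, the marker GMT and a ground-truth JSON are written there.
#' @return A list with elements `bundle` (concatenated `expression_bundle`),
#'   `gene_expression` (gene x sample matrix before probe noise), `masks`
#'   (list `left`, `right`), `marker_sets` (`gene_sets`), `truth` (list:
#'   `planted` tibble with signed effects, `affected_samples`,
#'   `donor_offsets`, `enriched_marker_sets`) and `config`.
#' @export
simulate_atlas <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  G <- config$n_genes
  D <- config$n_donors
  S <- config$samples_per_donor
  N <- D * S
  genes <- sprintf("G%04d", seq_len(G))
  donors <- sprintf("D%d", seq_len(D))
  donor_of <- rep(donors, each = S)
  sample_ids <- paste0(rep(donors, each = S), "_S",
                       formatC(rep(seq_len(S), D), width = 3, flag = "0"))

  ## spatial design -----------------------------------------------------
  n_inside <- round_half_up(config$mask_fraction * N)
  if (n_inside < 1) stop_imagetx("degenerate design: no samples inside mask")
  inside <- rep(FALSE, N)
  inside[sample.int(N, n_inside)] <- TRUE
  coords <- matrix(NA_real_, N, 3)
  inner <- sim_world_box(margin = -0.5)
  for (ax in 1:3) {
    coords[inside, ax] <- runif(n_inside, inner$lo[ax], inner$hi[ax])
  }
  outer <- sim_world_box(margin = 2.5)
  n_out <- N - n_inside
  got <- 0
  out_xyz <- matrix(NA_real_, n_out, 3)
  while (got < n_out) {
    m <- (n_out - got) * 2 + 8
    cand <- cbind(runif(m, -38, -1.5), runif(m, -46, 46), runif(m, -38, 38))
    in_box <- cand[, 1] >= outer$lo[1] & cand[, 1] <= outer$hi[1] &
      cand[, 2] >= outer$lo[2] & cand[, 2] <= outer$hi[2] &
      cand[, 3] >= outer$lo[3] & cand[, 3] <= outer$hi[3]
    keep <- cand[!in_box, , drop = FALSE]
    take <- min(nrow(keep), n_out - got)
    if (take > 0) out_xyz[(got + 1):(got + take), ] <- keep[seq_len(take), ]
    got <- got + take
  }
  coords[!inside, ] <- out_xyz
  structures <- paste0("ctx-", c("precentral", "postcentral",
                                 "superiorfrontal", "rostralmiddlefrontal",
                                 "superiortemporal", "lateraloccipital",
                                 "supramarginal", "precuneus"))
  structure_of <- sample(structures, N, replace = TRUE)
  samples <- tibble(sample_id = sample_ids,
                    donor_id = donor_of,
                    structure_label = structure_of,
                    mni_x = coords[, 1], mni_y = coords[, 2],
                    mni_z = coords[, 3],
                    hemisphere = "left")

  ## gene-level expression ----------------------------------------------
  planted_idx <- sort(sample.int(G, config$n_planted_de))
  sign_vec <- rep(c(1, -1), length.out = config$n_planted_de)
  baseline <- rnorm(G, mean = 7, sd = 1)
  offsets <- matrix(rnorm(D * G, sd = config$donor_batch_sd), D, G,
                    dimnames = list(donors, genes))
  rho <- config$intra_donor_correlation
  shared <- matrix(rnorm(D * G), D, G)
  di <- match(donor_of, donors)
  X <- matrix(baseline, G, N) + t(offsets[di, , drop = FALSE]) +
    config$residual_sd * (sqrt(rho) * t(shared[di, , drop = FALSE]) +
                            sqrt(1 - rho) * matrix(rnorm(G * N), G, N))
  if (config$n_planted_de > 0) {
    shift <- config$de_effect_size * config$residual_sd
    X[planted_idx, inside] <- X[planted_idx, inside] + sign_vec * shift
  }
  dimnames(X) <- list(genes, sample_ids)

  ## probe level ---------------------------------------------------------
  # probe counts are allocated deterministically from the configured
  # proportions so that shapes and identifiers depend on the config only,
  # never on the seed
  pp <- config$probes_per_gene_distribution
  alloc <- diff(c(0, round_half_up(cumsum(pp / sum(pp)) * G)))
  n_probes_gene <- rep(as.integer(names(pp)), times = alloc)
  gene_rep <- rep(seq_len(G), n_probes_gene)
  probe_rank <- sequence(n_probes_gene)
  probe_ids <- sprintf("%s_p%d", genes[gene_rep], probe_rank)
  P <- length(probe_ids)
  best <- probe_rank == 1L
  noise_sd <- ifelse(best, 0.1, runif(P, 0.4, 1.0))
  bias <- ifelse(best, 0, rnorm(P, sd = 0.3))
  PE <- X[gene_rep, , drop = FALSE] + bias +
    matrix(rnorm(P * N), P, N) * noise_sd
  rownames(PE) <- probe_ids
  dr <- config$detection_rate_range
  det_rate <- ifelse(best, dr[2], runif(P, dr[1], dr[2]))
  DET <- matrix(as.numeric(rbinom(P * N, 1L, rep(det_rate, N))), P, N,
                dimnames = list(probe_ids, sample_ids))
  probes <- tibble(probe_id = probe_ids,
                   gene_symbol = genes[gene_rep],
                   is_annotated = TRUE)

  ## RNA-seq companion ---------------------------------------------------
  rna_cols <- which(di <= config$rnaseq_donors)
  rnaseq <- X[, rna_cols, drop = FALSE] +
    matrix(rnorm(G * length(rna_cols), sd = config$rnaseq_noise_sd),
           G, length(rna_cols))

  ## marker sets ----------------------------------------------------------
  planted_genes <- genes[planted_idx]
  nonplanted <- setdiff(genes, planted_genes)
  specs <- config$marker_set_specs
  members <- purrr::pmap(list(specs$set_size, specs$n_overlap),
                         function(sz, ov) {
                           c(sample(planted_genes, ov),
                             sample(nonplanted, sz - ov))
                         })
  marker_sets <- gene_sets(specs$set_name,
                           description = sprintf("synthetic marker set (%d/%d planted)",
                                                 specs$n_overlap,
                                                 specs$set_size),
                           genes = members)
  expected_sig <- specs$set_name[specs$set_size >= 5 &
                                   specs$n_overlap / specs$set_size >= 0.6]

  masks <- sim_mask_pair()
  truth <- list(planted = tibble(gene = planted_genes,
                                 sign = sign_vec,
                                 effect = sign_vec * config$de_effect_size *
                                   config$residual_sd),
                affected_samples = sample_ids[inside],
                donor_offsets = offsets,
                enriched_marker_sets = expected_sig)

  per_donor <- lapply(donors, function(d) {
    idx <- which(donor_of == d)
    structure(list(
      probes = probes,
      samples = samples[idx, ],
      expression = PE[, idx, drop = FALSE],
      detection = DET[, idx, drop = FALSE],
      rnaseq = if (match(d, donors) <= config$rnaseq_donors)
        rnaseq[, intersect(colnames(rnaseq), sample_ids[idx]),
               drop = FALSE] else NULL),
      class = "expression_bundle")
  })
  bundle <- bind_bundles(per_donor)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(donors)) {
      write_expression_bundle(per_donor[[k]],
                              file.path(dir, paste0("donor_", donors[k])))
    }
    write_mask(masks$left, file.path(dir, "mask_left.nii"))
    write_mask(masks$right, file.path(dir, "mask_right.nii"))
    write_gmt(marker_sets, file.path(dir, "markers.gmt"))
    jsonlite::write_json(
      list(planted = truth$planted,
           affected_samples = truth$affected_samples,
           enriched_marker_sets = truth$enriched_marker_sets,
           seed = config$seed),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }

  list(bundle = bundle, gene_expression = X, masks = masks,
       marker_sets = marker_sets, truth = truth, config = config)
}

#' Simulate a disease transcriptomic-signature table
#'
#' Emits a `(gene, disease, logFC, q)` table with controlled numbers of genes
#' passing the disease-set gates (`q <= 0.05` and `|logFC| > 0.1`), plus
#' non-qualifying filler rows that sit on the wrong side of exactly one gate.
#' Explicit gene lists may be supplied to control sharing between diseases.
#'
#' @param genes Character vector, the gene universe.
#' @param diseases Tibble with columns `disease`, `n_higher`, `n_lower` and
#'   optional list-columns `higher_genes`, `lower_genes` pinning specific
#'   member genes.
#' @param seed Integer seed.
#' @param n_filler Non-qualifying rows added per disease.
#' @return Tibble `gene`, `disease`, `logFC`, `q`.
#' @export
simulate_disease_signatures <- function(genes, diseases, seed = 1L,
                                        n_filler = 20L) {
  set.seed(seed)
  diseases <- as_tibble(diseases)
  purrr::map_dfr(
    seq_len(nrow(diseases)),
    function(i) {
      row <- diseases[i, ]
      hi <- if ("higher_genes" %in% names(row) &&
                !is.null(row$higher_genes[[1]])) {
        row$higher_genes[[1]]
      } else sample(genes, row$n_higher)
      lo_pool <- setdiff(genes, hi)
      lo <- if ("lower_genes" %in% names(row) &&
                !is.null(row$lower_genes[[1]])) {
        row$lower_genes[[1]]
      } else sample(lo_pool, row$n_lower)
      if (length(intersect(hi, lo)) > 0) {
        stop_imagetx("a gene cannot be both higher and lower for one disease")
      }
      fill <- sample(setdiff(genes, c(hi, lo)), n_filler)
      half <- length(fill) %/% 2
      tibble(
        gene = c(hi, lo, fill),
        disease = row$disease,
        logFC = c(runif(length(hi), 0.15, 1.5),
                  runif(length(lo), -1.5, -0.15),
                  runif(half, -0.1, 0.1),               # fails |logFC| gate
                  runif(length(fill) - half, -1.5, 1.5)), # fails q gate
        q = c(runif(length(hi), 0, 0.05),
              runif(length(lo), 0, 0.05),
              runif(half, 0, 0.05),
              runif(length(fill) - half, 0.06, 1)))
    })
}
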