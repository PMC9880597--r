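#' Progenitor domain specification
#'
#' Describes one rostro-caudal progenitor domain: where it sits on the
#' rostro-caudal axis, the anchor gene that marks it, its co-expressed
#' markers, and how softly its expression falls off beyond the domain
#' boundary.
#'
#' @param name Domain label (e.g. `"rTh.Pro"`).
#' @param position Rostro-caudal coordinate in `[0, 1]`.
#' @param anchor_gene Anchor marker symbol.
#' @param marker_genes Character vector of co-expressed marker symbols
#'   (disjoint across domains).
#' @param mu_high In-domain mean expression on the counts-per-thousand scale.
#' @param mu_low Out-of-domain background mean (CPT).
#' @param boundary_softness Width of the exponential falloff of expression
#'   with distance from the domain along the axis; `0` gives a hard
#'   indicator boundary.
#' @return A list of class `domain_spec`.
#' @export
domain_spec <- function(name, position, anchor_gene, marker_genes,
                        mu_high = 20, mu_low = 0, boundary_softness = 0.05) {
  assert_that(mu_high > mu_low && mu_low >= 0,
              "domain means must satisfy mu_high > mu_low >= 0")
  assert_that(position >= 0 && position <= 1,
              "domain position must lie in [0, 1]")
  assert_that(boundary_softness >= 0, "boundary_softness must be >= 0")
  structure(list(name = name, position = position,
                 anchor_gene = anchor_gene,
                 marker_genes = as.character(marker_genes),
                 mu_high = mu_high, mu_low = mu_low,
                 boundary_softness = boundary_softness),
            class = "domain_spec")
}

#' Default progenitor domains
#'
#' Five rostro-caudally ordered domains of the embryonic thalamus, each
#' anchored by its classical marker (Nkx2-2 for the rostral thalamic
#' progenitors, Olig2 and Dbx1 for the two caudal domains, Rspo3 for the
#' epithalamic domain, Pax7 for the pretectal one).  Shh-responsive genes
#' are placed as markers of the two rostral-most, Shh-proximal domains so
#' that genotype contrasts propagate to the Shh response score.  Remaining
#' marker symbols are synthetic placeholders.
#'
#' @param boundary_softness Falloff width shared by all domains.
#' @return A list of `domain_spec` objects ordered rostral to caudal.
#' @export
default_domains <- function(boundary_softness = 0.05) {
  list(
    domain_spec("rTh.Pro", 0.10, "Nkx2-2",
                c("Gli1", "Ptch1", "Pdlim3", "Fst",
                  paste0("rThPro.mk", 1:4)),
                boundary_softness = boundary_softness),
    domain_spec("cTh.Pro1", 0.30, "Olig2",
                c("Zdbf2", "Hs3st1", "Slc38a11",
                  paste0("cThPro1.mk", 1:5)),
                boundary_softness = boundary_softness),
    domain_spec("cTh.Pro2", 0.50, "Dbx1",
                paste0("cThPro2.mk", 1:8),
                boundary_softness = boundary_softness),
    domain_spec("epiTh.Pro", 0.70, "Rspo3",
                c("Macrod2", paste0("epiThPro.mk", 1:7)),
                boundary_softness = boundary_softness),
    domain_spec("preT.Pro", 0.90, "Pax7",
                paste0("preTPro.mk", 1:8),
                boundary_softness = boundary_softness)
  )
}

#' Full description of a synthetic dataset
#'
#' The generative model: each cell belongs to a progenitor domain (sampled
#' by `weights`, down-weighted per-domain in mutants by `depletion`), sits
#' at a uniform position within its domain's segment of the rostro-caudal
#' axis, and expresses each domain's genes at a mean that decays with
#' distance from that domain.  Housekeeping genes carry a fixed expression
#' ladder, mitochondrial genes a fixed share of the library, and cycling
#' cells receive an additive G2/M program.  Counts are negative binomial
#' with a shared dispersion, scaled to lognormal library sizes.
#'
#' @param domains Ordered list of [domain_spec()] objects.
#' @param weights Control-genotype sampling weights over domains (normalised
#'   internally).
#' @param n_cells_control,n_cells_mutant Cells per genotype.
#' @param depletion Named vector of multiplicative factors applied to the
#'   mutant sampling weights (domains absent from the map keep factor 1).
#' @param nb_dispersion Shared NB size parameter `theta`
#'   (variance `mu + mu^2/theta`).
#' @param libsize_meanlog,libsize_sdlog Lognormal library-size parameters;
#'   defaults centre the per-cell UMI median near 4,900.
#' @param n_housekeeping,n_mito Numbers of housekeeping and `mt-` genes.
#' @param mito_frac_mean Expected mitochondrial UMI fraction (default 2.7%).
#' @param cycling_frac Fraction of cells carrying the G2/M program.
#' @param g2m_genes,g2m_effect Cell-cycle program gene set and its additive
#'   CPT effect in cycling cells.
#' @param lineage Bifurcation description for [simulate_lineage()]: a list
#'   with `branch_markers` (two symbols), `branch_props`, `pt_noise`,
#'   `progenitor_genes`, `progenitor_mu`, `branch_mu`.
#' @param ambient Barcode-rank tail description: list with `n_empty` and
#'   `mean_umis`.
#' @param rng_seed Integer seed; fixes every random draw.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(domains = default_domains(),
                            weights = c(0.2, 0.2, 0.3, 0.2, 0.1),
                            n_cells_control = 1800,
                            n_cells_mutant = 1800,
                            depletion = c(rTh.Pro = 0.1, cTh.Pro1 = 0.1),
                            nb_dispersion = 2,
                            libsize_meanlog = log(4891),
                            libsize_sdlog = 0.39,
                            n_housekeeping = 40,
                            n_mito = 10,
                            mito_frac_mean = 0.027,
                            cycling_frac = 0.3,
                            g2m_genes = c("Mki67", "Top2a", "Ccnb1", "Cdk1",
                                          "Ube2c", "Birc5", "Aurka", "Plk1",
                                          "Cenpa", "Bub1", "Ccna2", "Cdc20",
                                          "Nusap1", "Cks2", "Hmgb2"),
                            g2m_effect = 10,
                            lineage = list(branch_markers = c("Sox2", "Foxp2"),
                                           branch_props = c(0.5, 0.5),
                                           pt_noise = 0.1,
                                           progenitor_genes = paste0("Prog.", 1:10),
                                           progenitor_mu = 15,
                                           branch_mu = 15),
                            ambient = list(n_empty = 5000, mean_umis = 50),
                            rng_seed = 0L) {
  spec <- list(domains = domains, weights = weights,
               n_cells_control = n_cells_control,
               n_cells_mutant = n_cells_mutant,
               depletion = depletion, nb_dispersion = nb_dispersion,
               libsize_meanlog = libsize_meanlog,
               libsize_sdlog = libsize_sdlog,
               n_housekeeping = n_housekeeping, n_mito = n_mito,
               mito_frac_mean = mito_frac_mean, cycling_frac = cycling_frac,
               g2m_genes = g2m_genes, g2m_effect = g2m_effect,
               lineage = lineage, ambient = ambient,
               rng_seed = as.integer(rng_seed))
  validate_simulation_spec(spec)
  class(spec) <- "simulation_spec"
  spec
}

validate_simulation_spec <- function(spec) {
  nm <- vapply(spec$domains, `[[`, "", "name")
  assert_that(!anyDuplicated(nm), "domain names must be unique")
  pos <- vapply(spec$domains, `[[`, 0, "position")
  assert_that(all(diff(pos) > 0),
              "domain positions must be strictly increasing")
  all_markers <- unlist(lapply(spec$domains,
                               function(d) c(d$anchor_gene, d$marker_genes)))
  assert_that(!anyDuplicated(all_markers),
              "marker sets must be disjoint across domains")
  assert_that(length(spec$weights) == length(spec$domains),
              "one sampling weight per domain is required")
  assert_that(all(spec$weights > 0), "sampling weights must be positive")
  assert_that(all(spec$depletion > 0), "depletion factors must be positive")
  assert_that(all(names(spec$depletion) %in% nm),
              "depletion map keys must be domain names")
  assert_that(spec$cycling_frac >= 0 && spec$cycling_frac <= 1,
              "cycling_frac must lie in [0, 1]")
  assert_that(spec$nb_dispersion > 0, "nb_dispersion must be positive")
  invisible(spec)
}

#' @rdname simulation_spec
#' @param path YAML file path.
#' @export
read_simulation_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$domains)) {
    raw$domains <- lapply(raw$domains, function(d) do.call(domain_spec, d))
  }
  known <- names(formals(simulation_spec))
  do.call(simulation_spec, raw[intersect(names(raw), known)])
}

#' @rdname simulation_spec
#' @param spec A `simulation_spec`.
#' @export
write_simulation_spec <- function(spec, path) {
  out <- unclass(spec)
  out$domains <- lapply(out$domains, unclass)
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- internal generative machinery -----------------------------------------

domain_segments <- function(domains) {
  pos <- vapply(domains, `[[`, 0, "position")
  mid <- (pos[-1] + pos[-length(pos)]) / 2
  data.frame(name = vapply(domains, `[[`, "", "name"),
             lo = c(0, mid), hi = c(mid, 1))
}

# Exponential-falloff proximity of axis positions p to the segment [lo, hi];
# 1 inside the segment, exp(-dist/softness)-shaped outside, indicator at 0.
segment_proximity <- function(p, lo, hi, softness) {
  dist <- pmax(0, lo - p, p - hi)
  if (softness == 0) return(as.numeric(dist == 0))
  2 / (1 + exp(dist / softness))
}

hk_gene_names <- function(n) sprintf("Hk.%02d", seq_len(n))
mito_gene_names <- function(n) sprintf("mt-Rna%02d", seq_len(n))

# Housekeeping CPT ladder: fixed log-spaced means so the backbone of the
# library is deterministic across runs.
hk_mu <- function(n) exp(seq(log(2), log(25), length.out = n))

# Sample NB counts for an expected-CPT matrix (genes x cells), scaling each
# cell so its expected total equals its lognormal library size.
sample_counts <- function(mu_cpt, libsizes, theta) {
  n_cells <- length(libsizes)
  if (n_cells == 0) {
    return(Matrix::Matrix(0, nrow = nrow(mu_cpt), ncol = 0, sparse = TRUE,
                          dimnames = list(rownames(mu_cpt), character(0))))
  }
  tot <- colSums(mu_cpt)
  mu <- sweep(mu_cpt, 2, libsizes / tot, `*`)
  counts <- matrix(rnbinom(length(mu), size = theta, mu = as.vector(mu)),
                   nrow = nrow(mu), dimnames = dimnames(mu_cpt))
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

sim_barcodes <- function(n, prefix = "BC") {
  if (n == 0) return(character(0))
  sprintf("%s%06d", prefix, seq_len(n))
}

# Expected CPT matrix for domain-model cells at given axis positions, plus
# housekeeping / mito / cell-cycle programs.
domain_mu_cpt <- function(spec, positions, cycling) {
  segs <- domain_segments(spec$domains)
  gene_blocks <- lapply(spec$domains, function(d) c(d$anchor_gene, d$marker_genes))
  genes <- c(unlist(gene_blocks), hk_gene_names(spec$n_housekeeping),
             mito_gene_names(spec$n_mito), spec$g2m_genes)
  n_cells <- length(positions)
  mu <- matrix(0, nrow = length(genes), ncol = n_cells,
               dimnames = list(genes, NULL))
  for (i in seq_along(spec$domains)) {
    d <- spec$domains[[i]]
    prox <- segment_proximity(positions, segs$lo[i], segs$hi[i],
                              d$boundary_softness)
    mu[gene_blocks[[i]], ] <- rep(d$mu_low + (d$mu_high - d$mu_low) * prox,
                                  each = length(gene_blocks[[i]]))
  }
  mu[hk_gene_names(spec$n_housekeeping), ] <- hk_mu(spec$n_housekeeping)
  mu[spec$g2m_genes, ] <- 1
  if (any(cycling)) {
    mu[spec$g2m_genes, cycling] <- 1 + spec$g2m_effect
  }
  mu <- set_mito_share(mu, spec)
  mu
}

# Give mito genes the expected share mito_frac_mean of each cell's library,
# whatever the rest of the cell's programs add up to.
set_mito_share <- function(mu, spec) {
  mito <- mito_gene_names(spec$n_mito)
  other <- colSums(mu[setdiff(rownames(mu), mito), , drop = FALSE])
  mu[mito, ] <- rep(other * spec$mito_frac_mean /
                      (1 - spec$mito_frac_mean) / spec$n_mito,
                    each = spec$n_mito)
  mu
}

qc_columns <- function(counts) {
  list(n_umis = Matrix::colSums(counts),
       n_genes = Matrix::colSums(counts > 0),
       mito_frac = mito_fraction(counts))
}

finish_dataset <- function(counts, genotype, timepoint, truth,
                           sample_id = "sim") {
  qc <- qc_columns(counts)
  cells <- cell_table(colnames(counts), sample_id, genotype, timepoint)
  cells$n_umis <- as.integer(qc$n_umis)
  cells$n_genes <- as.integer(qc$n_genes)
  cells$mito_frac <- qc$mito_frac
  structure(list(counts = counts, cells = cells, truth = truth),
            class = "simulated_dataset")
}

# ---- user-facing simulators ------------------------------------------------

#' Simulate a graded field of progenitor domains
#'
#' One genotype's worth of cells drawn from the domain model of a
#' [simulation_spec()]: each cell gets a domain (by the control sampling
#' weights), a uniform position within the domain's axis segment, and NB
#' counts around the distance-graded expected expression.  A
#' `cycling_frac` subset of cells carries the additive G2/M program.
#'
#' @param spec A `simulation_spec`.
#' @param n_cells Number of cells (default `spec$n_cells_control`).
#' @param genotype Genotype recorded in the cell table.
#' @param timepoint Timepoint recorded in the cell table.
#' @param sample_id Sample identifier recorded in the cell table.
#' @param seed Seed override (default `spec$rng_seed`).
#' @return A list with `counts` (sparse gene-by-cell matrix), `cells`
#'   (metadata incl. QC fields) and `truth` (barcode, domain, position,
#'   cycling).
#' @export
simulate_progenitor_field <- function(spec, n_cells = spec$n_cells_control,
                                      genotype = "control",
                                      timepoint = "E12.5",
                                      sample_id = "sim",
                                      seed = spec$rng_seed) {
  validate_simulation_spec(spec)
  segs <- domain_segments(spec$domains)
  with_rng(seed, {
    dom_idx <- sample.int(length(spec$domains), n_cells, replace = TRUE,
                          prob = spec$weights / sum(spec$weights))
    positions <- runif(n_cells, segs$lo[dom_idx], segs$hi[dom_idx])
    cycling <- runif(n_cells) < spec$cycling_frac
    libsizes <- rlnorm(n_cells, spec$libsize_meanlog, spec$libsize_sdlog)
    mu <- domain_mu_cpt(spec, positions, cycling)
    counts <- sample_counts(mu, libsizes, spec$nb_dispersion)
    colnames(counts) <- sim_barcodes(n_cells)
    truth <- data.frame(barcode = colnames(counts),
                        domain = segs$name[dom_idx],
                        position = positions, cycling = cycling,
                        stringsAsFactors = FALSE)
    finish_dataset(counts, genotype, timepoint, truth, sample_id)
  })
}

#' Sample domain labels for a control/mutant pair (no counts)
#'
#' The composition layer of the generative model on its own: per-cell
#' domain labels for both genotypes, with mutant sampling weights
#' multiplied by the per-domain depletion factors and renormalised.  Used
#' when only composition (not expression) is under study.
#'
#' @inheritParams simulate_progenitor_field
#' @return A data.frame with columns `barcode`, `genotype`, `domain`.
#' @export
simulate_genotype_labels <- function(spec, seed = spec$rng_seed) {
  validate_simulation_spec(spec)
  nm <- vapply(spec$domains, `[[`, "", "name")
  w_ctrl <- spec$weights / sum(spec$weights)
  depl <- setNames(rep(1, length(nm)), nm)
  depl[names(spec$depletion)] <- spec$depletion
  w_mut <- w_ctrl * depl
  assert_that(sum(w_mut) > 0, "depleted weights sum to zero")
  w_mut <- w_mut / sum(w_mut)
  with_rng(seed, {
    dc <- sample(nm, spec$n_cells_control, replace = TRUE, prob = w_ctrl)
    dm <- sample(nm, spec$n_cells_mutant, replace = TRUE, prob = w_mut)
    data.frame(
      barcode = c(sim_barcodes(spec$n_cells_control, "BCC"),
                  sim_barcodes(spec$n_cells_mutant, "BCM")),
      genotype = rep(c("control", "mutant"),
                     c(spec$n_cells_control, spec$n_cells_mutant)),
      domain = c(dc, dm), stringsAsFactors = FALSE)
  })
}

#' Analytic odds ratio implied by a simulation spec
#'
#' For a group of domains `G`, the population odds ratio contrasting
#' control versus mutant membership in `G`:
#' `OR = (p_c / (1 - p_c)) / (p_m / (1 - p_m))` where `p_c`, `p_m` are the
#' control and (depleted, renormalised) mutant probabilities of `G`.
#'
#' @param spec A `simulation_spec`.
#' @param group Character vector of domain names.
#' @return The exact odds ratio.
#' @export
analytic_odds_ratio <- function(spec, group) {
  nm <- vapply(spec$domains, `[[`, "", "name")
  assert_that(all(group %in% nm), "group must name domains in the spec")
  w_ctrl <- spec$weights / sum(spec$weights)
  depl <- setNames(rep(1, length(nm)), nm)
  depl[names(spec$depletion)] <- spec$depletion
  w_mut <- w_ctrl * depl
  w_mut <- w_mut / sum(w_mut)
  p_c <- sum(w_ctrl[match(group, nm)])
  p_m <- sum(w_mut[match(group, nm)])
  (p_c / (1 - p_c)) / (p_m / (1 - p_m))
}

#' Simulate a control/mutant genotype pair
#'
#' Draws both genotypes from the domain model, with the mutant's domain
#' sampling weights multiplied by the depletion factors.  The analytic odds
#' ratio for the depleted domain group is attached as attribute
#' `analytic_or`.
#'
#' @inheritParams simulate_progenitor_field
#' @return As [simulate_progenitor_field()], with both genotypes in
#'   `cells$genotype` and per-cell truth.
#' @export
simulate_genotype_pair <- function(spec, timepoint = "E12.5",
                                   seed = spec$rng_seed) {
  validate_simulation_spec(spec)
  labels <- simulate_genotype_labels(spec, seed = seed)
  segs <- domain_segments(spec$domains)
  dom_idx <- match(labels$domain, segs$name)
  with_rng(offset_seed(seed, 1L), {
    n <- nrow(labels)
    positions <- runif(n, segs$lo[dom_idx], segs$hi[dom_idx])
    cycling <- runif(n) < spec$cycling_frac
    libsizes <- rlnorm(n, spec$libsize_meanlog, spec$libsize_sdlog)
    mu <- domain_mu_cpt(spec, positions, cycling)
    counts <- sample_counts(mu, libsizes, spec$nb_dispersion)
    colnames(counts) <- labels$barcode
    truth <- data.frame(barcode = labels$barcode, domain = labels$domain,
                        position = positions, cycling = cycling,
                        stringsAsFactors = FALSE)
    out <- finish_dataset(counts, labels$genotype, timepoint, truth)
    attr(out, "analytic_or") <-
      if (length(spec$depletion) > 0)
        analytic_odds_ratio(spec, names(spec$depletion)) else 1
    out
  })
}

#' Simulate a bifurcating post-mitotic lineage
#'
#' Cells progress along pseudotime `t in [0, 1]`; a shared progenitor
#' program decays linearly in `t` while each cell's branch marker (default
#' Sox2 for branch A, Foxp2 for branch B) rises linearly on its own branch
#' only, so the two branch markers are anti-correlated among late cells.
#' Expression responds to `t` plus Gaussian noise of sd `pt_noise`
#' (truncated to `[0, 1]`); the recorded truth keeps the noiseless `t`.
#'
#' @inheritParams simulate_progenitor_field
#' @return A list with `counts`, `cells`, and `truth` (barcode, branch,
#'   pseudotime, cycling).
#' @export
simulate_lineage <- function(spec, n_cells = spec$n_cells_control,
                             genotype = "control", timepoint = "E14.5",
                             seed = spec$rng_seed) {
  validate_simulation_spec(spec)
  lin <- spec$lineage
  assert_that(!is.null(lin) && length(lin$branch_markers) == 2,
              "lineage spec with two branch markers is required")
  genes <- c(lin$progenitor_genes, lin$branch_markers,
             hk_gene_names(spec$n_housekeeping),
             mito_gene_names(spec$n_mito), spec$g2m_genes)
  with_rng(seed, {
    t_true <- runif(n_cells)
    branch <- sample(c("A", "B"), n_cells, replace = TRUE,
                     prob = lin$branch_props)
    t_eff <- pmin(1, pmax(0, t_true + if (lin$pt_noise > 0)
      rnorm(n_cells, 0, lin$pt_noise) else 0))
    cycling <- (t_true < 0.5) & (runif(n_cells) < spec$cycling_frac)
    mu <- matrix(0, nrow = length(genes), ncol = n_cells,
                 dimnames = list(genes, NULL))
    mu[lin$progenitor_genes, ] <- rep(lin$progenitor_mu * (1 - t_eff),
                                      each = length(lin$progenitor_genes))
    mu[lin$branch_markers[1], branch == "A"] <-
      lin$branch_mu * t_eff[branch == "A"]
    mu[lin$branch_markers[2], branch == "B"] <-
      lin$branch_mu * t_eff[branch == "B"]
    mu[hk_gene_names(spec$n_housekeeping), ] <- hk_mu(spec$n_housekeeping)
    mu[spec$g2m_genes, ] <- 1
    if (any(cycling)) mu[spec$g2m_genes, cycling] <- 1 + spec$g2m_effect
    mu <- set_mito_share(mu, spec)
    libsizes <- rlnorm(n_cells, spec$libsize_meanlog, spec$libsize_sdlog)
    counts <- sample_counts(mu, libsizes, spec$nb_dispersion)
    colnames(counts) <- sim_barcodes(n_cells)
    truth <- data.frame(barcode = colnames(counts), branch = branch,
                        pseudotime = t_true, cycling = cycling,
                        stringsAsFactors = FALSE)
    finish_dataset(counts, genotype, timepoint, truth)
  })
}

#' Simulate a barcode-rank UMI distribution
#'
#' Real cells draw lognormal library sizes; ambient barcodes draw from a
#' geometric-tailed NB around `ambient$mean_umis`, producing the bimodal
#' curve whose knee the QC module detects.
#'
#' @inheritParams simulate_progenitor_field
#' @param n_real Number of real cells (default `spec$n_cells_control`).
#' @return A list with `umis` (integer vector over all nonzero barcodes,
#'   unsorted) and `n_real`.
#' @export
simulate_barcode_ranks <- function(spec, n_real = spec$n_cells_control,
                                   seed = spec$rng_seed) {
  validate_simulation_spec(spec)
  amb <- spec$ambient
  assert_that(!is.null(amb), "ambient spec is required")
  with_rng(seed, {
    real <- pmax(1, round(rlnorm(n_real, spec$libsize_meanlog,
                                 spec$libsize_sdlog)))
    empty <- if (amb$n_empty > 0) {
      rnbinom(amb$n_empty, size = 1, mu = amb$mean_umis)
    } else integer(0)
    empty <- empty[empty > 0]
    list(umis = c(real, empty), n_real = n_real)
  })
}
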