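#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator plants a sparse
#' regulator-to-site network: each m6A site is controlled by a small number
#' of trans regulators, site methylation is an affine function of
#' log1p-transformed regulator expression plus Gaussian noise (clipped below
#' at zero), and m6A-seq window counts are Poisson draws with IP enrichment
#' inside planted peak spans.
#'
#' @param n_cells number of cells (observations).
#' @param n_regulators number of trans regulator genes.
#' @param n_sites number of m6A sites.
#' @param regulators_per_site number of regulators with nonzero effect per
#'   site (sparsity of the planted network).
#' @param effect_size_sd standard deviation of the planted regression
#'   coefficients (on the log1p expression scale).
#' @param noise_sd standard deviation of the additive Gaussian noise on site
#'   methylation levels.
#' @param seq_depth expected total mapped reads per m6A-seq library.
#' @param enrichment_fold IP/input rate ratio inside planted peak spans
#'   (must exceed 1).
#' @param log_mean,log_sd location and scale of the log-normal expression
#'   marginals (`meanlog`/`sdlog` of [stats::rlnorm()]).
#' @param dropout probability that an expression value is zeroed
#'   (zero-inflation); off by default.
#' @param seed integer seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 50, n_regulators = 10, n_sites = 5)
sim_config <- function(n_cells = 1000L, n_regulators = 100L, n_sites = 50L,
                       regulators_per_site = 3L, effect_size_sd = 1,
                       noise_sd = 0.1, seq_depth = 1e6L,
                       enrichment_fold = 4, log_mean = 1, log_sd = 1,
                       dropout = 0, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              n_regulators = as.integer(n_regulators),
              n_sites = as.integer(n_sites),
              regulators_per_site = as.integer(regulators_per_site),
              effect_size_sd = effect_size_sd, noise_sd = noise_sd,
              seq_depth = as.integer(seq_depth),
              enrichment_fold = enrichment_fold,
              log_mean = log_mean, log_sd = log_sd, dropout = dropout,
              seed = as.integer(seed))
  for (f in c("n_cells", "n_regulators", "n_sites", "regulators_per_site",
              "seq_depth")) {
    if (!is_count(cfg[[f]])) stop2("sim_config: `", f, "` must be a positive integer")
  }
  if (!is_number(cfg$effect_size_sd) || cfg$effect_size_sd <= 0)
    stop2("sim_config: `effect_size_sd` must be a positive real")
  if (!is_number(cfg$noise_sd) || cfg$noise_sd < 0)
    stop2("sim_config: `noise_sd` must be nonnegative")
  if (!is_number(cfg$enrichment_fold) || cfg$enrichment_fold <= 1)
    stop2("sim_config: `enrichment_fold` must exceed 1")
  if (cfg$regulators_per_site > cfg$n_regulators)
    stop2("sim_config: `regulators_per_site` cannot exceed `n_regulators`")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop2("sim_config: `dropout` must be in [0, 1)")
  if (abs(cfg$seed) > 2^31 - 100)
    stop2("sim_config: `seed` too large for the 32-bit RNG stream")
  structure(cfg, class = "sim_config")
}

#' Generate regulator expression
#'
#' Cells-by-regulators matrix with independent log-normal marginals
#' (heavy right tail, as in TPM-scale expression). Optional dropout zeroes
#' entries at the configured rate.
#'
#' @param cfg a [sim_config()].
#' @return Numeric matrix, `n_cells` rows (cells) by `n_regulators` columns,
#'   with dimnames populated.
#' @export
gen_regulator_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    x <- matrix(rlnorm(cfg$n_cells * cfg$n_regulators,
                       meanlog = cfg$log_mean, sdlog = cfg$log_sd),
                nrow = cfg$n_cells, ncol = cfg$n_regulators)
    if (cfg$dropout > 0)
      x[runif(length(x)) < cfg$dropout] <- 0
    x
  }) -> x
  dimnames(x) <- list(sprintf("cell_%04d", seq_len(cfg$n_cells)),
                      sprintf("REG%04d", seq_len(cfg$n_regulators)))
  x
}

mean_log1p_lognormal <- function(meanlog, sdlog) {
  stats::integrate(function(z) log1p(exp(z)) * stats::dnorm(z, meanlog, sdlog),
                   meanlog - 8 * sdlog, meanlog + 8 * sdlog)$value
}

#' Plant a sparse regulator-to-site network
#'
#' Each site receives `regulators_per_site` distinct regulators acting on
#' log1p expression. Coefficients have random sign and magnitude uniform on
#' `[0.5, 1.5] * effect_size_sd`: every planted regulator has a genuine
#' effect (a regulator with a near-zero coefficient would not be part of
#' the network), and the marginal coefficient SD is close to
#' `effect_size_sd`.
#' Intercepts are drawn so that each site's expected level is uniform on
#' 2..4 — the scale of winscore levels of called peaks, which by
#' construction exceed the enrichment cutoff of 2: the drawn baseline is
#' offset by minus the coefficient sum times the expected log1p expression,
#' keeping site levels positive except in rare tails (levels are clipped
#' at zero by [gen_m6a_levels()]).
#'
#' @param cfg a [sim_config()].
#' @param site_ids optional character vector of site identifiers.
#' @return A list of class `planted_network` with per-site regulator
#'   indices, coefficients, intercepts (offset-compensated), baselines
#'   (`base`, the expected site levels), and the noise SD.
#' @export
planted_network <- function(cfg, site_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(site_ids)) site_ids <- sprintf("site_%03d", seq_len(cfg$n_sites))
  if (length(site_ids) != cfg$n_sites)
    stop2("planted_network: `site_ids` must have length n_sites")
  mu_lx <- mean_log1p_lognormal(cfg$log_mean, cfg$log_sd)
  withr::with_seed(cfg$seed + 2L, {
    regs <- lapply(seq_len(cfg$n_sites), function(i)
      sort(sample.int(cfg$n_regulators, cfg$regulators_per_site)))
    coefs <- lapply(seq_len(cfg$n_sites), function(i)
      sample(c(-1, 1), cfg$regulators_per_site, replace = TRUE) *
        cfg$effect_size_sd * runif(cfg$regulators_per_site, 0.5, 1.5))
    base <- runif(cfg$n_sites, 2, 4)
    list(regs, coefs, base)
  }) -> drawn
  icpt <- drawn[[3]] -
    vapply(drawn[[2]], sum, numeric(1)) * mu_lx
  structure(list(site_ids = site_ids, regulators = drawn[[1]],
                 coefficients = drawn[[2]], intercept = icpt,
                 base = drawn[[3]], mean_log1p_expr = mu_lx,
                 noise_sd = cfg$noise_sd, n_regulators = cfg$n_regulators,
                 seed = cfg$seed),
            class = "planted_network")
}

#' Generate ground-truth m6A levels from a planted network
#'
#' `y[site, cell] = intercept + sum(coef * log1p(expr[cell, reg])) + noise`,
#' clipped below at zero (methylation levels are nonnegative enrichment
#' scores).
#'
#' @param expr cells-by-regulators expression matrix whose columns cover all
#'   regulator indices referenced by `net`.
#' @param net a [planted_network()].
#' @param seed seed for the noise draw; defaults to a stream derived from
#'   the network's seed.
#' @return Sites-by-cells numeric matrix (an m6A peak/site matrix).
#' @export
gen_m6a_levels <- function(expr, net, seed = net$seed + 3L) {
  stopifnot(inherits(net, "planted_network"), is.matrix(expr))
  idx <- unlist(net$regulators)
  if (any(idx < 1L) || any(idx > ncol(expr)))
    stop2("gen_m6a_levels: regulator index out of range for `expr`")
  lx <- log1p(expr)
  n_sites <- length(net$site_ids)
  y <- matrix(0, nrow = n_sites, ncol = nrow(expr),
              dimnames = list(net$site_ids, rownames(expr)))
  for (s in seq_len(n_sites)) {
    y[s, ] <- net$intercept[s] +
      drop(lx[, net$regulators[[s]], drop = FALSE] %*% net$coefficients[[s]])
  }
  if (net$noise_sd > 0) {
    withr::with_seed(seed,
      y <- y + matrix(rnorm(length(y), 0, net$noise_sd), nrow = n_sites))
  }
  pmax(y, 0)
}

#' Generate a transcript annotation
#'
#' One transcript per gene with 5'UTR, CDS and 3'UTR spans given in
#' transcript coordinates (5' to 3'), plus a relative expression abundance
#' used by the read-count generator.
#'
#' @param cfg a [sim_config()].
#' @param n_transcripts number of transcripts; defaults to `cfg$n_sites`
#'   (one planted site per transcript).
#' @param seed RNG stream.
#' @return Data frame with columns `transcript_id`, `gene_id`, `strand`,
#'   `utr5_len`, `cds_len`, `utr3_len`, `length`, `expression`.
#' @export
gen_annotation <- function(cfg, n_transcripts = cfg$n_sites,
                           seed = cfg$seed + 5L) {
  stopifnot(inherits(cfg, "sim_config"), is_count(n_transcripts))
  withr::with_seed(seed, {
    utr5 <- sample(100:300, n_transcripts, replace = TRUE)
    cds <- sample(900:2400, n_transcripts, replace = TRUE)
    utr3 <- sample(300:900, n_transcripts, replace = TRUE)
    expr <- rlnorm(n_transcripts, cfg$log_mean, cfg$log_sd)
    strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
    list(utr5, cds, utr3, expr, strand)
  }) -> d
  data.frame(transcript_id = sprintf("TX%04d", seq_len(n_transcripts)),
             gene_id = sprintf("GENE%04d", seq_len(n_transcripts)),
             strand = d[[5]],
             utr5_len = d[[1]], cds_len = d[[2]], utr3_len = d[[3]],
             length = d[[1]] + d[[2]] + d[[3]],
             expression = d[[4]],
             stringsAsFactors = FALSE)
}

#' Plant m6A peak spans on transcripts
#'
#' Places one span per transcript, start aligned to the sliding-window step
#' so that planted spans tile whole windows. Site identifiers follow the
#' `gene:start-end` convention used by peak matrices.
#'
#' @param annotation a [gen_annotation()] table.
#' @param cfg a [sim_config()]; supplies the default IP enrichment fold.
#' @param width span width in bases.
#' @param step alignment grid (use the quantification step size).
#' @param seed RNG stream.
#' @return Data frame with `site_id`, `transcript_id`, `gene_id`, `start`,
#'   `end` (0-based half-open, transcript coordinates) and `fold`.
#' @export
plant_sites <- function(annotation, cfg, width = 200L, step = 50L,
                        seed = cfg$seed + 6L) {
  stopifnot(is.data.frame(annotation), inherits(cfg, "sim_config"))
  if (any(annotation$length < width))
    stop2("plant_sites: some transcripts are shorter than the span width")
  withr::with_seed(seed, {
    max_slot <- (annotation$length - width) %/% step
    start <- step * vapply(max_slot, function(m) sample.int(m + 1L, 1L) - 1L,
                           integer(1))
  })
  out <- data.frame(transcript_id = annotation$transcript_id,
                    gene_id = annotation$gene_id,
                    start = as.integer(start),
                    end = as.integer(start + width),
                    fold = cfg$enrichment_fold,
                    stringsAsFactors = FALSE)
  out$site_id <- sprintf("%s:%d-%d", out$gene_id, out$start, out$end)
  out[, c("site_id", "transcript_id", "gene_id", "start", "end", "fold")]
}

#' Generate paired IP/input window counts
#'
#' Input counts are Poisson with rates proportional to transcript expression
#' times window width, scaled so the expected library size equals
#' `cfg$seq_depth`. IP rates are the input rates multiplied, inside planted
#' spans, by the span's enrichment fold (partial window overlap scales the
#' fold proportionally). Reported library sizes are the realized totals, so
#' per-window counts always sum to the library size. Overlapping sliding
#' windows are drawn independently, a deliberate simulation simplification.
#'
#' @param annotation a [gen_annotation()] table.
#' @param spans planted spans from [plant_sites()]; a `fold` column
#'   overrides `cfg$enrichment_fold` per span.
#' @param cfg a [sim_config()].
#' @param quant a [quant_config()] defining the window grid.
#' @param seed RNG stream.
#' @return List with `ip` and `input`, each a [window_counts()] object.
#' @export
gen_window_counts <- function(annotation, spans, cfg, quant = quant_config(),
                              seed = cfg$seed + 4L) {
  stopifnot(is.data.frame(annotation), is.data.frame(spans),
            inherits(cfg, "sim_config"))
  tx_len <- setNames(annotation$length, annotation$transcript_id)
  bad <- spans$end > tx_len[spans$transcript_id] | spans$start < 0
  if (any(is.na(bad)) || any(bad))
    stop2("gen_window_counts: planted span outside its transcript")
  win <- make_windows(annotation, quant)
  expr <- setNames(annotation$expression, annotation$transcript_id)
  base_rate <- expr[win$chrom] * (win$end - win$start)
  base_rate <- base_rate / sum(base_rate) * cfg$seq_depth
  fold <- if ("fold" %in% names(spans)) spans$fold else
    rep(cfg$enrichment_fold, nrow(spans))
  factor <- rep(1, nrow(win))
  for (k in seq_len(nrow(spans))) {
    on_tx <- win$chrom == spans$transcript_id[k]
    ov <- pmax(0, pmin(win$end, spans$end[k]) - pmax(win$start, spans$start[k]))
    f <- 1 + (fold[k] - 1) * ov / (win$end - win$start)
    factor <- ifelse(on_tx, pmax(factor, f), factor)
  }
  withr::with_seed(seed, {
    input_counts <- rpois(nrow(win), base_rate)
    ip_counts <- rpois(nrow(win), base_rate * factor)
    list(input_counts, ip_counts)
  }) -> cts
  list(ip = window_counts(win, cts[[2]], sum(cts[[2]])),
       input = window_counts(win, cts[[1]], sum(cts[[1]])))
}

IUPAC_RNA <- list(A = "A", C = "C", G = "G", U = "U", T = "U",
                  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
                  W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
                  B = c("C", "G", "U"), D = c("A", "G", "U"),
                  H = c("A", "C", "U"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "U"))

#' Generate position probability matrices around a consensus
#'
#' Builds `n_motifs` PPMs (rows A, C, G, U) for an IUPAC consensus: each
#' column starts from the uniform distribution over the bases the IUPAC code
#' allows, then is mixed with an independent Dirichlet(1,1,1,1) draw with
#' weight `perturbation`. Columns sum to one exactly.
#'
#' @param n_motifs number of PPMs; the default mirrors a 42-motif cis
#'   feature panel.
#' @param consensus IUPAC RNA string (T is read as U).
#' @param perturbation mixing weight in `[0, 1)`; 0 gives the unperturbed
#'   consensus PPM.
#' @param seed RNG stream.
#' @return Named list of 4-by-L matrices with rownames A, C, G, U.
#' @export
gen_ppms <- function(n_motifs = 42L, consensus = "GGACU", perturbation = 0.1,
                     seed = 1L) {
  stopifnot(is_count(n_motifs), nchar(consensus) >= 1)
  bases <- c("A", "C", "G", "U")
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters_ %in% names(IUPAC_RNA)))
    stop2("gen_ppms: invalid IUPAC character in consensus: ",
          paste(setdiff(letters_, names(IUPAC_RNA)), collapse = ", "))
  L <- length(letters_)
  base_ppm <- vapply(letters_, function(ch) {
    p <- setNames(numeric(4), bases)
    allowed <- IUPAC_RNA[[ch]]
    p[allowed] <- 1 / length(allowed)
    p
  }, numeric(4))
  withr::with_seed(seed, {
    lapply(seq_len(n_motifs), function(i) {
      if (perturbation > 0) {
        g <- matrix(rgamma(4 * L, 1), nrow = 4)
        g <- sweep(g, 2, colSums(g), "/")
        p <- (1 - perturbation) * base_ppm + perturbation * g
      } else p <- base_ppm
      p <- sweep(p, 2, colSums(p), "/")
      dimnames(p) <- list(bases, NULL)
      p
    })
  }) -> ppms
  names(ppms) <- sprintf("motif_%02d", seq_len(n_motifs))
  ppms
}

#' Simulate a complete dataset
#'
#' Convenience wrapper tying all generators together: annotation, planted
#' spans, regulator expression, planted network, ground-truth m6A levels
#' (rows named after the planted spans), IP/input window counts, and cis
#' PPMs. When `fold_from_levels` is TRUE, each span's IP enrichment fold is
#' `1 + mean site level`, coupling the m6A-seq signal to the planted truth
#' so winscore quantification and model predictions can be correlated.
#'
#' @param cfg a [sim_config()].
#' @param quant a [quant_config()].
#' @param fold_from_levels couple IP enrichment to planted m6A levels.
#' @param n_motifs,consensus passed to [gen_ppms()].
#' @return List with `annotation`, `spans`, `expr`, `net`, `m6a` (truth),
#'   `counts` (list ip/input), `ppms`, and the `cfg` used.
#' @export
simulate_dataset <- function(cfg = sim_config(), quant = quant_config(),
                             fold_from_levels = FALSE, n_motifs = 42L,
                             consensus = "GGACU") {
  ann <- gen_annotation(cfg)
  spans <- plant_sites(ann, cfg, step = quant$step)
  expr <- gen_regulator_expression(cfg)
  net <- planted_network(cfg, site_ids = spans$site_id)
  m6a <- gen_m6a_levels(expr, net)
  if (fold_from_levels) spans$fold <- 1 + rowMeans(m6a)
  counts <- gen_window_counts(ann, spans, cfg, quant)
  ppms <- gen_ppms(n_motifs = n_motifs, consensus = consensus,
                   seed = cfg$seed + 7L)
  list(annotation = ann, spans = spans, expr = expr, net = net, m6a = m6a,
       counts = counts, ppms = ppms, cfg = cfg)
}
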