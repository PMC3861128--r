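#' Build a toy single-chromosome genome with a tiling probe grid
#'
#' Lays out `n_genes` non-overlapping gene spans on one chromosome, assigns a
#' random strand to each, and covers the chromosome with a tiling probe grid
#' whose spacing is jittered uniformly by +/-20% around `probe_spacing`, so the
#' *median* inter-probe spacing matches the target while downstream code can
#' never assume a regular grid. Gene coordinates are 0-based half-open, the
#' convention used throughout the package.
#'
#' @param n_genes Number of genes to place (>= 1).
#' @param chrom_length Chromosome length in bp. Must leave room for the genes
#'   plus at least 1 kb of intergenic gap on average, otherwise the request is
#'   rejected as over-dense.
#' @param probe_spacing Target median probe spacing in bp (default 55, the
#'   spacing of the tiling platform the pipeline is designed for).
#' @param gene_length_range Length range (bp) genes are drawn from.
#' @param chrom Chromosome name.
#' @param seed Integer seed; the same seed and arguments give a bit-identical
#'   genome.
#'
#' @return An object of class `toy_genome`: a list with `$genes` (tibble:
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`), `$probes` (tibble:
#'   `chrom`, `start`, `end`), and the scalar fields `chrom`, `length`,
#'   `probe_spacing`.
#' @export
#' @examples
#' g <- make_toy_genome(n_genes = 5, chrom_length = 50000, seed = 1)
#' g$genes
make_toy_genome <- function(n_genes, chrom_length, probe_spacing = 55,
                            gene_length_range = c(1500, 4000),
                            chrom = "chrSim", seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  chrom_length <- check_count(chrom_length, "chrom_length", min = 1000)
  probe_spacing <- check_number(probe_spacing, "probe_spacing", min = 1, strict_min = TRUE)
  set.seed(seed)

  lengths <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
  min_gaps <- 1000 * (n_genes + 1)
  if (sum(lengths) + min_gaps > chrom_length) {
    abort(paste0(
      "cannot place ", n_genes, " genes with >= 1 kb mean gaps on a ",
      chrom_length, " bp chromosome; request is over-dense."
    ))
  }
  free <- chrom_length - sum(lengths)
  w <- runif(n_genes + 1)
  gaps <- floor(free * w / sum(w))
  starts <- cumsum(gaps[seq_len(n_genes)] + c(0, lengths[-n_genes]))
  ends <- starts + lengths
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(ends),
    strand = strand,
    tss = as.integer(ifelse(strand == "+", starts, ends - 1L))
  )

  n_draw <- ceiling(chrom_length / (0.8 * probe_spacing)) + 2
  steps <- probe_spacing * runif(n_draw, 0.8, 1.2)
  pstart <- round(c(0, cumsum(steps)))
  pstart <- pstart[pstart < chrom_length - 50]
  probes <- tibble(chrom = chrom, start = as.integer(pstart),
                   end = as.integer(pstart + 50L))

  structure(
    list(chrom = chrom, length = chrom_length, probe_spacing = probe_spacing,
         genes = genes, probes = probes),
    class = "toy_genome"
  )
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", x$chrom, ": ", x$length, " bp, ",
      nrow(x$genes), " genes, ", nrow(x$probes), " probes (target spacing ",
      x$probe_spacing, " bp)\n", sep = "")
  invisible(x)
}

#' Describe acetylation-gain domains to plant in a simulated experiment
#'
#' A spike specification names the genes that gain an acetylation domain under
#' drug A only, drug B only, or under both drugs (the shared set the cross-drug
#' intersection is meant to recover), together with the domain geometry and the
#' log2 effect size.
#'
#' @param shared,a_only,b_only Character vectors of gene ids.
#' @param width Domain width in bp; must cover at least 3 probes at the
#'   genome's target spacing (checked when the spec is applied to a genome).
#' @param effect Log2 elevation inside the domain (> 0; gains only).
#' @param offset Domain start relative to the gene TSS, in bp downstream.
#'
#' @return An object of class `spike_spec`.
#' @export
spike_spec <- function(shared = character(), a_only = character(),
                       b_only = character(), width = 1000, effect = 1.0,
                       offset = 0) {
  effect <- check_number(effect, "effect", min = 0, strict_min = TRUE)
  width <- check_number(width, "width", min = 1)
  offset <- check_number(offset, "offset", min = 0)
  all_ids <- c(shared, a_only, b_only)
  if (anyDuplicated(all_ids)) {
    abort("a gene id may appear in only one of shared / a_only / b_only.")
  }
  structure(
    list(shared = as.character(shared), a_only = as.character(a_only),
         b_only = as.character(b_only), width = width, effect = effect,
         offset = offset),
    class = "spike_spec"
  )
}

# smooth gene-proximal baseline elevation: plateau with raised-cosine shoulders
taper_profile <- function(mid, dstart, dend, ramp = 150) {
  inside <- as.numeric(mid >= dstart & mid < dend)
  left <- mid < dstart & mid >= dstart - ramp
  right <- mid >= dend & mid < dend + ramp
  out <- inside
  out[left] <- 0.5 * (1 + cos(pi * (dstart - mid[left]) / ramp))
  out[right] <- 0.5 * (1 + cos(pi * (mid[right] - dend + 1) / ramp))
  out
}

# strand-aware TSS-anchored domain for one gene
spike_domain <- function(gene, offset, width) {
  if (gene$strand == "+") {
    c(gene$tss + offset, gene$tss + offset + width)
  } else {
    c(gene$tss - offset - width + 1, gene$tss - offset + 1)
  }
}

#' Simulate a two-channel tiling ChIP experiment with planted domains
#'
#' Generates raw IP and input probe intensities for three conditions (control,
#' drug A, drug B) over a toy genome. All conditions share a baseline
#' acetylation landscape with a smooth elevation over each gene's TSS-proximal
#' kilobase; the drug conditions additionally carry the planted gain domains
#' from the spike specification. Gaussian probe noise (log2 scale, sd
#' `noise_sd`) is drawn independently per probe and replicate, and the ground
#' truth (domain intervals and spiked gene sets) is returned alongside so every
#' downstream stage has an oracle.
#'
#' @param genome A [make_toy_genome()] object.
#' @param spikes A [spike_spec()].
#' @param noise_sd Per-probe, per-replicate sd of the IP/input log2 ratio
#'   noise (log2 units, > 0).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param baseline_effect Log2 elevation of the TSS-proximal baseline landscape
#'   present in every condition.
#' @param base_log2 Mean log2 input-channel intensity.
#' @param seed Integer seed.
#'
#' @return An object of class `tiling_sim`: `$channels` (tibble: `condition`
#'   in control/drugA/drugB, `replicate`, `chrom`, `start`, `end`, `ip`,
#'   `input`), `$truth` (list with `$domains` tibble and the spiked gene id
#'   sets), plus the simulation parameters.
#' @export
simulate_tiling_experiment <- function(genome, spikes, noise_sd = 0.5,
                                       n_replicates = 2, baseline_effect = 0.8,
                                       base_log2 = 10, seed = 1) {
  stopifnot(inherits(genome, "toy_genome"), inherits(spikes, "spike_spec"))
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (spikes$width < 3 * genome$probe_spacing) {
    abort("spike width must cover at least 3 probes (width >= 3 * probe_spacing).")
  }
  unknown <- setdiff(c(spikes$shared, spikes$a_only, spikes$b_only),
                     genome$genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("spiked gene id(s) not in genome: ", paste(unknown, collapse = ", ")))
  }
  set.seed(seed)

  probes <- genome$probes
  mid <- (probes$start + probes$end) / 2
  m <- nrow(probes)

  baseline <- rep(0, m)
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    dom <- spike_domain(g, 0, 1000)
    baseline <- baseline + baseline_effect * taper_profile(mid, dom[1], dom[2])
  }

  spiked_genes <- list(A = c(spikes$shared, spikes$a_only),
                       B = c(spikes$shared, spikes$b_only))
  domain_rows <- list()
  spike_landscape <- list(A = rep(0, m), B = rep(0, m))
  for (drug in c("A", "B")) {
    for (gid in spiked_genes[[drug]]) {
      g <- genome$genes[genome$genes$gene_id == gid, ]
      dom <- spike_domain(g, spikes$offset, spikes$width)
      hit <- mid >= dom[1] & mid < dom[2]
      spike_landscape[[drug]][hit] <- spike_landscape[[drug]][hit] + spikes$effect
      domain_rows[[paste(drug, gid)]] <- tibble(
        gene_id = gid, drug = drug, chrom = genome$chrom,
        start = as.integer(max(dom[1], 0)), end = as.integer(dom[2]),
        effect = spikes$effect,
        shared = gid %in% spikes$shared
      )
    }
  }
  domains <- bind_rows(domain_rows)

  landscapes <- list(control = baseline,
                     drugA = baseline + spike_landscape$A,
                     drugB = baseline + spike_landscape$B)

  channels <- list()
  for (cond in names(landscapes)) {
    for (rep_i in seq_len(n_replicates)) {
      input_log2 <- rnorm(m, base_log2, 0.25)
      ratio <- landscapes[[cond]] + rnorm(m, 0, noise_sd)
      channels[[paste(cond, rep_i)]] <- tibble(
        condition = cond, replicate = rep_i,
        chrom = probes$chrom, start = probes$start, end = probes$end,
        ip = 2^(input_log2 + ratio), input = 2^input_log2
      )
    }
  }

  structure(
    list(
      channels = bind_rows(channels),
      truth = list(domains = domains, shared = spikes$shared,
                   a_only = spikes$a_only, b_only = spikes$b_only),
      genome = genome, spikes = spikes, noise_sd = noise_sd,
      n_replicates = n_replicates, baseline_effect = baseline_effect
    ),
    class = "tiling_sim"
  )
}

#' @export
print.tiling_sim <- function(x, ...) {
  cat("<tiling_sim> ", nrow(x$genome$probes), " probes x 3 conditions x ",
      x$n_replicates, " replicates; ", nrow(x$truth$domains),
      " planted domains (effect ", x$spikes$effect, ", noise sd ", x$noise_sd,
      ")\n", sep = "")
  invisible(x)
}

#' Extract one condition/replicate channel pair from a simulation
#'
#' @param sim A [simulate_tiling_experiment()] result.
#' @param condition One of `"control"`, `"drugA"`, `"drugB"`.
#' @param replicate Replicate number.
#' @return A tibble with `chrom`, `start`, `end`, `ip`, `input`.
#' @export
sim_channel <- function(sim, condition, replicate = 1) {
  stopifnot(inherits(sim, "tiling_sim"))
  out <- sim$channels[sim$channels$condition == condition &
                        sim$channels$replicate == replicate, ]
  if (nrow(out) == 0) abort("no such condition/replicate in the simulation.")
  out[, c("chrom", "start", "end", "ip", "input")]
}
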