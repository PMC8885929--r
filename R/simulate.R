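# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate metabolites with planted correlation modules
#'
#' Draws features from a Gaussian factor model so that blocks of features
#' share a latent factor: for a feature in a block,
#' `x = sqrt(between_r) * g + sqrt(within_r - between_r) * f_block +
#' sqrt(1 - within_r) * noise`, all factors standard normal per sample.
#' The expected correlation is `within_r` inside a block and `between_r`
#' across blocks. This emulates the block structure visible in metabolite
#' correlation heatmaps and gives module detection a known ground truth.
#'
#' @param n_samples number of samples.
#' @param block_sizes integer vector; its sum is the number of features.
#' @param within_r expected within-block correlation, in `(0, 1]`.
#' @param between_r expected between-block correlation,
#'   `0 <= between_r < within_r`.
#' @param seed RNG seed (generation is fully seed-deterministic).
#' @param negative_fraction fraction of features loading negatively on
#'   their block factor (anti-correlated members); default 0.
#' @return list with `table` (a [feature_table()], features `met<i>`,
#'   samples `s<j>`), `labels` (integer block labels), `design` (two
#'   balanced groups, for interface fidelity; the generator adds no group
#'   effect).
#' @export
make_planted_modules <- function(n_samples, block_sizes, within_r,
                                 between_r = 0, seed = 1,
                                 negative_fraction = 0) {
  if (within_r < 0 || within_r > 1 || between_r < 0 ||
      (between_r >= within_r && within_r > 0))
    stop("need 0 <= between_r < within_r <= 1 (0/0 = pure noise)")
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  with_seed(seed, {
    g <- stats::rnorm(n_samples)
    fac <- matrix(stats::rnorm(length(block_sizes) * n_samples),
                  length(block_sizes), n_samples)
    vals <- matrix(0, n, n_samples)
    sgn <- rep(1, n)
    if (negative_fraction > 0)
      for (b in seq_along(block_sizes)) {
        idx <- which(labels == b)
        nneg <- floor(length(idx) * negative_fraction)
        if (nneg) sgn[idx[seq_len(nneg)]] <- -1
      }
    for (i in seq_len(n)) {
      noise <- stats::rnorm(n_samples)
      vals[i, ] <- sqrt(between_r) * g +
        sgn[i] * sqrt(within_r - between_r) * fac[labels[i], ] +
        sqrt(1 - within_r) * noise
    }
    ft <- feature_table(vals,
                        feature_ids = sprintf("met%03d", seq_len(n)),
                        sample_ids = sprintf("s%02d", seq_len(n_samples)))
    design <- data.frame(
      sample_id = colnames(ft),
      group = rep(c("control", "treated"), length.out = n_samples),
      stringsAsFactors = FALSE)
    class(design) <- c("design_table", "data.frame")
    list(table = ft, labels = labels, design = design)
  })
}

#' Simulate pathway-structured genes and linked metabolites
#'
#' Emulates the shape of a two-condition transcriptomics + metabolomics
#' study (two groups, a handful of replicates per group, both omics
#' measured on the same samples): each pathway has one latent activity
#' factor per sample (a group effect plus Gaussian noise), its genes load
#' positively on that factor with additive noise, and each linked
#' metabolite follows a designated pathway's factor with a chosen sign.
#' Unlinked metabolites are pure noise. The returned truth record names
#' the driving pathway per metabolite for recovery tests.
#'
#' @param pathway_sizes named integer vector: pathway id -> number of
#'   genes.
#' @param linked_metabolites data.frame with columns `metabolite_id`,
#'   `pathway_id`, `sign` (+1/-1); may be empty.
#' @param n_unlinked number of pure-noise metabolites appended.
#' @param n_samples total samples, split into two balanced groups
#'   (default 10, i.e. 5 per condition).
#' @param noise_sd standard deviation of gene/metabolite noise around the
#'   factor (default 0.3; factors have unit noise scale plus the group
#'   shift).
#' @param group_shift difference between group means of every pathway
#'   factor (default 1.5, a clear but noisy condition effect).
#' @param seed RNG seed.
#' @return list with `genes`, `metabolites` ([feature_table()]s),
#'   `annotation` (gene `annotation_table` without a snapshot: kegg_id
#'   equals the gene id), `design`, `truth` (data.frame `metabolite_id`,
#'   `pathway_id`, `sign`; NA pathway for unlinked), `factors` (pathways
#'   x samples latent matrix).
#' @export
make_pathway_factor_data <- function(pathway_sizes, linked_metabolites,
                                     n_unlinked = 0, n_samples = 10,
                                     noise_sd = 0.3, group_shift = 1.5,
                                     seed = 1) {
  if (n_samples < 3L) stop("need at least 3 samples")
  pids <- names(pathway_sizes)
  if (is.null(pids)) stop("pathway_sizes must be named by pathway id")
  with_seed(seed, {
    grp <- rep(c(-0.5, 0.5), length.out = n_samples)
    fac <- matrix(stats::rnorm(length(pids) * n_samples),
                  length(pids), n_samples,
                  dimnames = list(pids, sprintf("s%02d",
                                                seq_len(n_samples))))
    fac <- fac + rep(grp * group_shift, each = length(pids))
    gene_ids <- character(0); gvals <- NULL; gpw <- character(0)
    for (p in pids) {
      ng <- pathway_sizes[[p]]
      loading <- stats::runif(ng, 0.6, 1)
      block <- loading %o% fac[p, ] +
        matrix(stats::rnorm(ng * n_samples, sd = noise_sd), ng)
      ids <- sprintf("%s_g%02d", p, seq_len(ng))
      gene_ids <- c(gene_ids, ids)
      gpw <- c(gpw, rep(p, ng))
      gvals <- rbind(gvals, block)
    }
    genes <- feature_table(gvals, feature_ids = gene_ids,
                           sample_ids = colnames(fac))
    annotation <- data.frame(feature_id = gene_ids, kegg_id = gene_ids,
                             match_score = 1, class_label = NA_character_,
                             pathway_ids = gpw, ambiguous = FALSE,
                             stringsAsFactors = FALSE)
    class(annotation) <- c("annotation_table", "data.frame")

    lm <- linked_metabolites
    met_ids <- as.character(lm$metabolite_id)
    mvals <- matrix(numeric(0), 0L, n_samples)
    for (i in seq_along(met_ids))
      mvals <- rbind(mvals, lm$sign[i] * fac[lm$pathway_id[i], ] +
                       stats::rnorm(n_samples, sd = noise_sd))
    truth <- data.frame(metabolite_id = met_ids,
                        pathway_id = as.character(lm$pathway_id),
                        sign = lm$sign, stringsAsFactors = FALSE)
    if (n_unlinked > 0) {
      uid <- sprintf("unlinked_m%02d", seq_len(n_unlinked))
      mvals <- rbind(mvals,
                     matrix(stats::rnorm(n_unlinked * n_samples),
                            n_unlinked))
      met_ids <- c(met_ids, uid)
      truth <- rbind(truth,
                     data.frame(metabolite_id = uid,
                                pathway_id = NA_character_, sign = NA_real_,
                                stringsAsFactors = FALSE))
    }
    metabolites <- feature_table(mvals, feature_ids = met_ids,
                                 sample_ids = colnames(fac))
    design <- data.frame(sample_id = colnames(fac),
                         group = ifelse(grp < 0, "control", "treated"),
                         stringsAsFactors = FALSE)
    class(design) <- c("design_table", "data.frame")
    list(genes = genes, metabolites = metabolites, annotation = annotation,
         design = design, truth = truth, factors = fac)
  })
}

#' Build the bundled miniature KEGG snapshot
#'
#' A small, fully synthetic snapshot in the package's flat-file dialect:
#' 20 compounds with synonym variants covering the matching cascade's
#' cases (letter case, stereo-descriptors, Greek letters, token
#' permutations), 30 worm-style genes with aliases, and 5 pathways
#' (branched-chain amino acid degradation, TCA cycle, oxidative
#' phosphorylation, beta-alanine metabolism, sphingolipid metabolism)
#' whose members all resolve. Content is fixed; `seed` only perturbs
#' nothing and exists for interface uniformity with the other generators.
#'
#' @param dir output directory for the snapshot files.
#' @param seed unused, accepted for generator-interface uniformity.
#' @return the loaded `kegg_snapshot`, invisibly.
#' @export
make_mini_kegg <- function(dir, seed = 1) {
  compounds <- list(
    C00183 = c("L-Valine", "Valine", "2-Amino-3-methylbutyric acid"),
    C00123 = c("L-Leucine", "Leucine"),
    C00407 = c("L-Isoleucine", "Isoleucine"),
    C00041 = c("L-Alanine", "Alanine"),
    C00099 = c("beta-Alanine", "β-Alanine", "3-Aminopropanoate"),
    C00149 = c("(S)-Malate", "L-Malic acid", "Malate"),
    C00091 = c("Succinyl-CoA", "Succinyl coenzyme A"),
    C00068 = c("Thiamin diphosphate", "Thiamine diphosphate", "ThPP"),
    C00777 = c("Retinoate", "Retinoic acid"),
    C00718 = c("Amylopectin"),
    C00025 = c("L-Glutamate", "Glutamate", "Glutamic acid"),
    C00049 = c("L-Aspartate", "Aspartic acid"),
    C00022 = c("Pyruvate", "Pyruvic acid"),
    C00042 = c("Succinate", "Succinic acid"),
    C00122 = c("Fumarate", "Fumaric acid"),
    C00036 = c("Oxaloacetate", "Oxalacetic acid"),
    C00158 = c("Citrate", "Citric acid"),
    C00024 = c("Acetyl-CoA", "Acetyl coenzyme A"),
    C00550 = c("Sphingomyelin", "SM"),
    C00346 = c("Ethanolamine phosphate", "Phosphoethanolamine"))
  gene_syms <- list(
    c("bcat-1", "BCAT1", "K02A4.1"), c("bckd-1A", "BCKDHA"),
    c("bckd-1B", "BCKDHB"), c("dbt-1", "DBT"), c("ech-6", "ECHS1"),
    c("acdh-1", "ACADSB"), c("hach-1", "HIBCH"), c("mce-1", "MCEE"),
    c("pcca-1", "PCCA"), c("pccb-1", "PCCB"),
    c("cts-1", "CS"), c("aco-2", "ACO2"), c("idh-1", "IDH1"),
    c("ogdh-1", "OGDH"), c("suca-1", "SUCLA"), c("sdha-1", "SDHA"),
    c("fum-1", "FH"), c("mdh-1", "MDH1"),
    c("nuo-1", "NDUFV1"), c("nuo-2", "NDUFS3"), c("cyc-1", "CYC1"),
    c("cco-1", "COX5B"), c("atp-2", "ATP5B"), c("atp-3", "ATP5O"),
    c("gta-1", "GABAT"), c("alh-7", "ALDH7A1"), c("pyd-1", "DPYD"),
    c("sptl-1", "SPTLC1"), c("cerk-1", "CERK"), c("asah-1", "ASAH1"))
  gene_ids <- sprintf("cel:CELE_%s", vapply(gene_syms, `[[`, "", 1L))
  genes <- stats::setNames(gene_syms, gene_ids)
  pathways <- list(
    cel00280 = list(name = "Valine, leucine and isoleucine degradation",
                    genes = gene_ids[1:10],
                    compounds = c("C00183", "C00123", "C00407", "C00091",
                                  "C00024")),
    cel00020 = list(name = "Citrate cycle (TCA cycle)",
                    genes = gene_ids[11:18],
                    compounds = c("C00149", "C00042", "C00122", "C00036",
                                  "C00158", "C00091", "C00022", "C00024",
                                  "C00068")),
    cel00190 = list(name = "Oxidative phosphorylation",
                    genes = gene_ids[19:24],
                    compounds = character(0)),
    cel00410 = list(name = "beta-Alanine metabolism",
                    genes = gene_ids[25:27],
                    compounds = c("C00099", "C00041", "C00049", "C00022")),
    cel00600 = list(name = "Sphingolipid metabolism",
                    genes = gene_ids[28:30],
                    compounds = c("C00550", "C00346")))
  snap <- structure(list(organism = "cel", compounds = compounds,
                         genes = genes, pathways = pathways),
                    class = "kegg_snapshot")
  write_snapshot(snap, dir)
  invisible(load_snapshot(dir))
}
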