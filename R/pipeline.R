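# End-to-end driver: simulate -> pseudoref -> popgen -> shared -> windows
# -> concord -> date, on a declarative config. Every stochastic stage draws
# from a named substream of the single master seed; outputs carry a
# manifest of file checksums and the exact config used (no timestamps, so
# identical runs are byte-identical).

.pipeline_stages <- c("simulate", "pseudoref", "popgen", "shared",
                      "windows", "concord", "date")

#' Validate a pipeline run configuration
#'
#' @param config Named list; see [run_pipeline()].
#' @return The config, normalized, invisibly; errors describe the first
#'   problem found.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop("config needs out_dir")
  if (is.null(config$seed)) stop("every stochastic stage needs an explicit seed; set config$seed")
  if (is.null(config$stages)) config$stages <- .pipeline_stages
  unknown <- setdiff(config$stages, .pipeline_stages)
  if (length(unknown)) stop("unknown stage name: ", paste(unknown, collapse = ", "))
  if (is.null(config$simulate$newick)) stop("config$simulate$newick is required")
  sim <- config$simulate
  for (f in c("Ne", "mu", "n_individuals")) if (is.null(sim[[f]]))
    stop("config$simulate$", f, " is required")
  invisible(config)
}

#' Read a pipeline config from YAML
#' @param path Path to a YAML config file.
#' @return Config list (validated).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages are executed in dependency order; each writes its outputs under
#' `config$out_dir` and all files are listed in `manifest.tsv` with md5
#' checksums, alongside the exact config (`config_used.yml`).
#'
#' Config fields: `out_dir`, `seed`, optional `stages`; `simulate` (with
#' `newick` species tree in generations, `Ne`, `mu`, `n_individuals` per
#' species, `window_length`, `n_windows`); optional `pseudoref`
#' (`quality_threshold`), `shared` (`focal`, `comparison`,
#' `exclude_singletons`), `windows` (`window_size`, `min_fraction`,
#' `min_informative`), `concord` (`n_quartets`), `date` (`lambda`,
#' `calibration_age`, `L_effective`, `outgroup`).
#'
#' @param config Named list (see above) or path to a YAML file.
#' @return data.frame manifest (file, md5), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  stages <- if (is.null(config$stages)) .pipeline_stages else config$stages
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  sim <- config$simulate
  sptree <- ape::read.tree(text = sim$newick)
  plan <- stats::setNames(rep(sim$n_individuals, ape::Ntip(sptree)),
                          sptree$tip.label)
  model <- species_tree_model(sptree, Ne = sim$Ne, mu = sim$mu,
                              sample_plan = plan,
                              window_length = sim$window_length %||% 5000L,
                              n_windows = sim$n_windows %||% 20L)

  ds <- NULL; smx <- NULL; sp_smx <- NULL; window_set <- NULL
  need <- function(stage, what, obj) {
    if (is.null(obj)) stop("stage '", stage, "' needs the ", what,
                           " artifact; include its upstream stage")
    obj
  }

  for (stage in .pipeline_stages[.pipeline_stages %in% stages]) {
    if (stage == "simulate") {
      ds <- simulate_dataset(model, seed = substream_seed(seed, "simulate"))
      paths <- write_dataset(ds, file.path(out, "sim"))
      for (p in paths) note(p)
    }
    if (stage == "pseudoref") {
      need("pseudoref", "simulated dataset", ds)
      # go through the file formats deliberately: the readers are part of
      # the pipeline under test
      ref <- read_fasta(file.path(out, "sim", "reference.fa"))
      vt <- read_vcf_genotypes(file.path(out, "sim", "variants.vcf.gz"))
      gq <- config$pseudoref$quality_threshold %||% 20
      pseudo <- lapply(ds$samples, function(s)
        build_pseudoreference(ref, vt, s, seed = substream_seed(seed, "pseudoref"),
                              quality_threshold = gq))
      species <- sub("_[0-9]+$", "", ds$samples)
      smx <- build_site_matrix(pseudo, groups = stats::setNames(species, ds$samples))
      # species-level matrix (first individual per species) for phylogenomics
      first <- !duplicated(species)
      sp_seqs <- pseudo[first]
      sp_smx <- build_site_matrix(sp_seqs,
                                  groups = stats::setNames(species[first],
                                                           ds$samples[first]))
      sp_smx$samples <- species[first]
      rownames(sp_smx$bases) <- species[first]
      names(sp_smx$groups) <- species[first]
      note(write_tsv(data.frame(sample = ds$samples, species = species),
                     file.path(out, "samples.tsv")))
      note(write_fasta(stats::setNames(apply(smx$bases, 1, paste, collapse = ""),
                                       smx$samples),
                       file.path(out, "site_matrix.fa")))
      note(write_tsv(data.frame(chrom = smx$chrom, pos = smx$pos),
                     file.path(out, "site_matrix_positions.tsv")))
    }
    if (stage == "popgen") {
      need("popgen", "site matrix", smx)
      pi_all <- nucleotide_diversity(smx)
      groups <- unique(unname(smx$groups))
      pi_groups <- vapply(groups, function(g)
        if (sum(smx$groups == g) >= 2) nucleotide_diversity(smx, g)$pi else NA_real_,
        numeric(1))
      note(write_tsv(data.frame(group = c("all", groups),
                                pi = c(pi_all$pi, pi_groups),
                                sites = pi_all$sites_used),
                     file.path(out, "pi.tsv")))
      multi <- groups[vapply(groups, function(g) sum(smx$groups == g) >= 2, logical(1))]
      if (length(multi) >= 2) {
        fst <- pairwise_fst_matrix(smx, multi)
        note(write_tsv(cbind(group = rownames(fst), as.data.frame(fst)),
                       file.path(out, "fst_matrix.tsv")))
      }
    }
    if (stage == "shared") {
      need("shared", "site matrix", smx)
      sh <- config$shared
      focal <- sh$focal %||% unique(unname(smx$groups))[1]
      comparison <- sh$comparison %||% setdiff(unique(unname(smx$groups)), focal)
      rows <- lapply(c(TRUE, FALSE), function(excl) {
        r <- shared_variable_sites_multi(smx, focal, comparison, excl)
        data.frame(focal = focal, comparison = paste(comparison, collapse = "+"),
                   singletons = r$singleton_mode,
                   n_focal_variable = r$n_focal_variable, n_shared = r$n_shared,
                   fraction = r$fraction)
      })
      note(write_tsv(do.call(rbind, rows), file.path(out, "shared_variation.tsv")))
    }
    if (stage == "windows") {
      need("windows", "species-level site matrix", sp_smx)
      w <- config$windows
      wt <- window_trees(sp_smx, window_size = w$window_size %||% 5000L,
                         min_fraction = w$min_fraction %||% 0.5,
                         min_informative = w$min_informative %||% 1L)
      window_set <- wt
      note(write_trees(wt$trees, file.path(out, "window_trees.nwk")))
      note(write_tsv(wt$windows, file.path(out, "window_provenance.tsv")))
    }
    if (stage == "concord") {
      wt <- window_set
      need("concord", "window trees", wt)
      ref <- model$tree
      gcf <- gene_concordance(ref, wt$trees)
      scf <- site_concordance(ref, sp_smx, n_quartets = config$concord$n_quartets %||% 200L,
                              seed = substream_seed(seed, "scf"))
      note(write_tsv(merge(gcf, scf, by = "split"), file.path(out, "concordance.tsv")))
    }
    if (stage == "date") {
      need("date", "species-level site matrix", sp_smx)
      dc <- config$date
      d <- jc69_matrix(sp_smx)
      if (!is.matrix(d)) stop("stage 'date': saturated distances")
      nj <- neighbor_joining(d)
      og <- dc$outgroup %||% sp_smx$samples[length(sp_smx$samples)]
      rooted <- ape::drop.tip(ape::root(nj, outgroup = og, resolve.root = TRUE), og)
      focal <- config$shared$focal %||% unique(unname(smx$groups %||% sp_smx$groups))[1]
      pi_focal <- if (!is.null(smx) && sum(smx$groups == focal) >= 2)
        nucleotide_diversity(smx, focal)$pi else 0
      L <- dc$L_effective %||% n_sites(sp_smx)
      cal <- dc$calibration_age %||% 56
      lam <- dc$lambda %||% 1
      chr_raw <- penalized_likelihood_date(rooted, calibration_age = cal,
                                           lambda = lam, L_effective = L,
                                           seed = substream_seed(seed, "date"))
      corr <- correct_ancestral_polymorphism(rooted, pi_focal)
      chr_cor <- penalized_likelihood_date(corr, calibration_age = cal,
                                           lambda = lam, L_effective = L,
                                           seed = substream_seed(seed, "date"))
      shifts <- age_shift_report(chr_cor, chr_raw)
      note(write_trees(chr_cor, file.path(out, "chronogram_corrected.nwk")))
      note(write_trees(chr_raw, file.path(out, "chronogram_uncorrected.nwk")))
      note(write_tsv(shifts, file.path(out, "age_shifts.tsv")))
    }
  }
  cfg_path <- file.path(out, "config_used.yml")
  yaml::write_yaml(config, cfg_path)
  note(cfg_path)
  rel <- sub("^/", "", substring(written, nchar(out) + 1L))
  manifest <- data.frame(file = rel, md5 = unname(tools::md5sum(written)))
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}

# shared_variable_sites over a multi-group comparison set: the comparison
# is the union of the listed groups
shared_variable_sites_multi <- function(sm, focal, comparison_groups,
                                        exclude_singletons = TRUE) {
  g <- sm$groups
  merged <- ifelse(g %in% comparison_groups, ".comparison", g)
  sm2 <- sm
  sm2$groups <- stats::setNames(merged, names(g))
  shared_variable_sites(sm2, focal, ".comparison", exclude_singletons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
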