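#' Build a pipeline configuration
#'
#' Merges user settings (an R list or a YAML file) over the defaults. The
#' `profile` expands to concrete parameters: `"desk"` uses 50 network
#' bootstraps and 2000 QTL permutations, sized for a single workstation;
#' `"paper"` documents the published-scale settings (900 bootstraps, 100000
#' permutations). Every resolved value is recorded in the run manifest.
#'
#' @param config a named list of overrides, or a path to a YAML file.
#' @param profile `"desk"` or `"paper"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), profile = c("desk", "paper")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  profile <- match.arg(profile)
  prof <- if (profile == "desk")
    list(n_bootstraps = 50L, n_sim = 2000L) else
      list(n_bootstraps = 900L, n_sim = 100000L)
  defaults <- list(
    seed = 1L,
    profile = profile,
    out_dir = "aqtlkit_run",
    stages = list(simulate = TRUE, preprocess = TRUE, network = TRUE,
                  activity = TRUE, mr = TRUE, qtl = TRUE, coloc = TRUE),
    simulate = list(),                      # sim_config() overrides
    network = list(n_bootstraps = prof$n_bootstraps, p_threshold = 1e-8,
                   n_null = 10000L, crit = 7.815),
    activity = list(min_targets = 25L, pleiotropy = TRUE,
                    min_common = 25L, alpha = 0.5),
    mr = list(step = 5L, n_repeats = 12L, cv_folds = 5L, ntree = 300L,
              ratio = 0.7),
    qtl = list(gwas_p_cutoff = 1e-5, cis_window = 1e6, n_pcs = 5L,
               n_sim = prof$n_sim, fdr = 0.05),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15,
                 window = 5e5))
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(defaults, config)
  class(cfg) <- "pipeline_config"
  cfg
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the full workflow
#'
#' Orchestrates simulate -> preprocess -> network -> activity -> master
#' regulators -> QTL -> colocalization under one configuration, writing
#' stage outputs and a run manifest (parameters, seeds, input/output file
#' hashes, wall times) into `out_dir`. All randomness derives from
#' `config$seed`, so rerunning with the same config reproduces identical
#' output hashes. A disabled stage is skipped and noted in the manifest;
#' later stages then consume the in-memory results of whichever stages ran.
#'
#' @param config a [pipeline_config] (or list/path accepted by it).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("aqtlkit")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, profile = config$profile,
                   parameters = config[setdiff(names(config), "stages")],
                   stages = list())
  results <- list()
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest$stages[[nm]] <<- c(list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 2)),
                                manifest$stages[[nm]])
    val
  }
  skip <- function(nm) manifest$stages[[nm]] <<- list(status = "skipped")
  fail_stage <- function(nm, e)
    stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
         call. = FALSE)

  # --- simulate ---------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    results$fixture <- tryCatch(t_stage("simulate", {
      sc <- do.call(sim_config, c(config$simulate,
                                  list(rng_seed = config$seed)))
      fx <- write_fixture(file.path(config$out_dir, "fixture"), sc)
      manifest$stages$simulate$files <- as.list(md5_of(unlist(fx$files)))
      fx
    }), error = function(e) fail_stage("simulate", e))
  } else skip("simulate")
  fx <- results$fixture
  if (is.null(fx)) stop("pipeline requires the simulate stage (or prior results)")

  # --- preprocess: reread the fixture through the package readers -------
  if (isTRUE(config$stages$preprocess)) {
    results$data <- tryCatch(t_stage("preprocess", {
      geno <- read_vcf(fx$files$vcf)
      exprv <- read_matrix_tsv(fx$files$expression)
      coords <- read.table(fx$files$gene_coords, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
      expr <- expression_matrix(exprv, "log2tpm", coords)
      pheno <- read.table(fx$files$phenotypes, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      regs <- read_regulator_list(fx$files$regulators)
      gwas <- read_gwas_tsv(fx$files$gwas)
      pcs <- genotype_pcs(geno, n_pcs = config$qtl$n_pcs)
      cov <- assemble_covariates(pheno, pcs)
      list(genotypes = geno, expression = expr, pheno = pheno,
           regulators = regs, gwas = gwas, covariates = cov)
    }), error = function(e) fail_stage("preprocess", e))
  } else {
    skip("preprocess")
    results$data <- list(genotypes = fx$genotypes, expression = fx$expression,
                         pheno = fx$phenotypes,
                         regulators = rownames(fx$truth$activities),
                         gwas = fx$gwas, covariates = NULL)
  }
  dat <- results$data

  # --- network ----------------------------------------------------------
  if (isTRUE(config$stages$network)) {
    results$network <- tryCatch(t_stage("network", {
      net <- bootstrap_consensus(dat$expression, dat$regulators,
                                 n_bootstraps = config$network$n_bootstraps,
                                 p_threshold = config$network$p_threshold,
                                 n_null = config$network$n_null,
                                 crit = config$network$crit,
                                 seed = child_seed(config$seed, 11))
      path <- file.path(config$out_dir, "network.tsv")
      write_network_tsv(net, path)
      manifest$stages$network$files <- as.list(md5_of(path))
      net
    }), error = function(e) fail_stage("network", e))
  } else skip("network")

  # --- activity ---------------------------------------------------------
  if (isTRUE(config$stages$activity)) {
    results$activity <- tryCatch(t_stage("activity", {
      interactome <- network_to_interactome(results$network, dat$expression)
      act <- infer_activities(dat$expression, interactome,
                              min_targets = config$activity$min_targets,
                              pleiotropy = config$activity$pleiotropy,
                              min_common = config$activity$min_common,
                              alpha = config$activity$alpha)
      rpath <- file.path(config$out_dir, "regulons.tsv")
      apath <- file.path(config$out_dir, "activities.tsv")
      write_regulon_tsv(interactome, rpath)
      write_matrix_tsv(unclass(act), apath)
      manifest$stages$activity$files <- as.list(md5_of(c(rpath, apath)))
      list(interactome = interactome, activities = act)
    }), error = function(e) fail_stage("activity", e))
  } else skip("activity")

  # --- master regulators -----------------------------------------------
  if (isTRUE(config$stages$mr)) {
    results$mr <- tryCatch(t_stage("mr", {
      act <- results$activity$activities
      phe <- setdiff(names(dat$pheno), c("sample_id", "age"))[1]
      curve <- cv_error_curve(act, dat$pheno, phe, step = config$mr$step,
                              n_repeats = config$mr$n_repeats,
                              cv_folds = config$mr$cv_folds,
                              ntree = config$mr$ntree,
                              seed = child_seed(config$seed, 21))
      K <- select_mr_count(curve)
      mrres <- train_final_model(act, dat$pheno, phe, K,
                                 seed = child_seed(config$seed, 22),
                                 ratio = config$mr$ratio,
                                 ntree = config$mr$ntree)
      cpath <- file.path(config$out_dir, "cv_curve.tsv")
      mpath <- file.path(config$out_dir, "mr_list.tsv")
      write.table(curve, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mrres$importance, mpath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$stages$mr$files <- as.list(md5_of(c(cpath, mpath)))
      list(curve = curve, K = K, result = mrres)
    }), error = function(e) fail_stage("mr", e))
  } else skip("mr")

  # --- QTL --------------------------------------------------------------
  if (isTRUE(config$stages$qtl)) {
    results$qtl <- tryCatch(t_stage("qtl", {
      geno <- dat$genotypes
      act <- results$activity$activities
      zexpr <- zscale(dat$expression)
      sig <- select_gwas_variants(dat$gwas, config$qtl$gwas_p_cutoff)
      coords <- dat$expression$gene_coords
      reg_genes <- coords[coords$gene_id %in% rownames(act), , drop = FALSE]
      names(reg_genes)[names(reg_genes) == "gene_id"] <- "gene_id"
      cisp <- cis_pairs(sig, reg_genes, config$qtl$cis_window)
      mr_genes <- reg_genes[reg_genes$gene_id %in% results$mr$result$mrs, ,
                            drop = FALSE]
      transp <- trans_pairs(sig, mr_genes, config$qtl$cis_window)
      cov <- dat$covariates
      scans <- list()
      for (kind in c("expression", "activity")) {
        traits <- if (kind == "expression")
          zexpr$values[rownames(act), , drop = FALSE] else unclass(act)
        for (md in c("cis", "trans")) {
          pr <- if (md == "cis") cisp else transp
          pr <- pr[pr$gene_id %in% rownames(traits), , drop = FALSE]
          nm <- paste(md, kind, sep = "_")
          if (nrow(pr) == 0) {
            scans[[nm]] <- NULL
            next
          }
          assoc <- qtl_scan(geno, traits, pr, cov)
          gw <- genewise_scan(geno, traits, pr, cov,
                              n_sim = config$qtl$n_sim, fdr = config$qtl$fdr,
                              seed = child_seed(config$seed,
                                                30 + match(nm, c("cis_expression",
                                                                 "trans_expression",
                                                                 "cis_activity",
                                                                 "trans_activity"))))
          scans[[nm]] <- list(assoc = assoc, genewise = gw)
          ap <- file.path(config$out_dir, paste0("qtl_", nm, "_assoc.tsv"))
          gp <- file.path(config$out_dir, paste0("qtl_", nm, "_genewise.tsv"))
          write.table(assoc, ap, sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(gw, gp, sep = "\t", quote = FALSE, row.names = FALSE)
          manifest$stages$qtl$files <-
            c(manifest$stages$qtl$files, as.list(md5_of(c(ap, gp))))
        }
      }
      strength <- NULL
      if (!is.null(scans$cis_expression) && !is.null(scans$cis_activity)) {
        cols <- c("variant_id", "gene_id", "p")
        tag <- function(x, md) {
          if (is.null(x)) return(NULL)
          out <- x$assoc[, cols]; out$mode <- md; out
        }
        strength <- compare_qtl_strength(
          rbind(tag(scans$cis_expression, "cis"),
                tag(scans$trans_expression, "trans")),
          rbind(tag(scans$cis_activity, "cis"),
                tag(scans$trans_activity, "trans")))
      }
      c(scans, list(strength = strength, cis_pairs = cisp,
                    trans_pairs = transp, gwas_sig = sig))
    }), error = function(e) fail_stage("qtl", e))
  } else skip("qtl")

  # --- colocalization ---------------------------------------------------
  if (isTRUE(config$stages$coloc)) {
    results$coloc <- tryCatch(t_stage("coloc", {
      gwas <- dat$gwas
      top <- gwas$variant_id[which.min(gwas$p)]
      act <- results$activity$activities
      dense <- dense_locus_scan(dat$genotypes, unclass(act), top,
                                window = config$coloc$window,
                                covariates = dat$covariates)
      # GWAS signal vs the strongest aQTL gene at the locus
      lead_gene <- dense$gene_id[which.min(dense$p)]
      sig_qtl <- dense[dense$gene_id == lead_gene, , drop = FALSE]
      sig_gwas <- gwas[gwas$variant_id %in% sig_qtl$variant_id, , drop = FALSE]
      tab <- coloc_matrix(list(gwas = sig_gwas, aqtl = sig_qtl),
                          p1 = config$coloc$p1, p2 = config$coloc$p2,
                          p12 = config$coloc$p12, W = config$coloc$W)
      cpath <- file.path(config$out_dir, "coloc.tsv")
      write.table(tab, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$coloc$files <- as.list(md5_of(cpath))
      list(table = tab, locus_variant = top, lead_gene = lead_gene)
    }), error = function(e) fail_stage("coloc", e))
  } else skip("coloc")

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
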