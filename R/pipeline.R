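# End-to-end orchestration: simulate -> cluster -> reconcile ->
# complements -> support (-> motifs), behind one entry point with a
# JSON manifest of outputs. All randomness flows from a single
# top-level seed via per-stage derived seeds recorded in the manifest;
# outputs carry no timestamps, so identical config + seed gives
# byte-identical files for the deterministic stages.

#' Assemble and check a pipeline configuration
#'
#' @param species_tree Path to the species-tree Newick file.
#' @param out_dir Output directory (created if missing).
#' @param n_families Number of families to simulate.
#' @param dup_rate,loss_rate Birth-death rates for the simulator.
#' @param thresholds P-value ladder, strictest (smallest) first.
#' @param c_d,c_l DL parsimony weights.
#' @param separator,position Leaf-naming convention.
#' @param n_replicates,n_nni Bootstrap-replicate stand-in parameters
#'   for the support stage.
#' @param seed Top-level integer seed.
#' @param stages Character vector of stages to run, in dependency
#'   order; subset of c("simulate", "cluster", "reconcile",
#'   "complements", "support").
#' @return A `run_config` list.
#' @export
run_config <- function(species_tree, out_dir, n_families = 5,
                       dup_rate = 0.5, loss_rate = 0.2,
                       thresholds = c(1e-35, 1e-15, 1e-6),
                       c_d = 1, c_l = 1, separator = "_",
                       position = "prefix", n_replicates = 20, n_nni = 1,
                       seed = 1,
                       stages = c("simulate", "cluster", "reconcile",
                                  "complements", "support")) {
  structure(list(species_tree = species_tree, out_dir = out_dir,
                 n_families = n_families, dup_rate = dup_rate,
                 loss_rate = loss_rate, thresholds = thresholds,
                 c_d = c_d, c_l = c_l, separator = separator,
                 position = position, n_replicates = n_replicates,
                 n_nni = n_nni, seed = as.integer(seed), stages = stages),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Report-only: returns a character vector of problems (empty when the
#' configuration is valid).
#'
#' @param config A `run_config`.
#' @return Character vector of error descriptions.
#' @export
validate_config <- function(config) {
  probs <- character(0)
  if (is.null(config$species_tree) || !file.exists(config$species_tree)) {
    probs <- c(probs, paste0("missing species tree file: ",
                             config$species_tree))
  }
  if (length(config$thresholds) &&
      is.unsorted(config$thresholds, strictly = TRUE)) {
    probs <- c(probs, "unsorted threshold ladder (need strictest first)")
  }
  if (!is.null(config$thresholds) &&
      (any(config$thresholds <= 0) || any(config$thresholds > 1))) {
    probs <- c(probs, "thresholds must lie in (0, 1]")
  }
  if (config$dup_rate < 0 || config$loss_rate < 0) {
    probs <- c(probs, "rates must be non-negative")
  }
  known <- c("simulate", "cluster", "reconcile", "complements", "support")
  unknown <- setdiff(config$stages, known)
  if (length(unknown)) {
    probs <- c(probs, paste0("unknown stage(s): ",
                             paste(unknown, collapse = ", ")))
  }
  probs
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order and writes every
#' output under `config$out_dir`, plus `manifest.json` listing each
#' file with its stage, parameters and md5 checksum.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  probs <- validate_config(config)
  if (length(probs)) stop("invalid config:\n  ", paste(probs, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  species_tree <- parse_newick(readLines(config$species_tree,
                                         warn = FALSE)[1],
                               expect_rooted = TRUE)
  validate_species_tree(species_tree, require_lengths = TRUE)

  # per-stage derived seeds (stable small offsets from the master seed)
  seed_of <- function(stage_idx) (config$seed * 1000L + stage_idx) %% 2147483647L

  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[c("n_families", "dup_rate",
                                                  "loss_rate", "thresholds",
                                                  "c_d", "c_l",
                                                  "n_replicates", "n_nni")],
                   stages = list(), files = list())
  record <- function(stage, path, extra = list()) {
    manifest$files[[basename(path)]] <<- c(
      list(stage = stage, path = basename(path),
           md5 = unname(tools::md5sum(path))), extra)
  }
  fail_stage <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    write_manifest(manifest, config$out_dir)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  families <- NULL; recs <- NULL
  run_stage <- function(stage, fun) {
    tryCatch({
      t0 <- proc.time()[["elapsed"]]
      fun()
      message(sprintf("[%s] done in %.2fs", stage,
                      proc.time()[["elapsed"]] - t0))
      manifest$stages[[stage]] <<- list(status = "ok")
    }, error = function(e) fail_stage(stage, e))
  }

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    set.seed(seed_of(1L))
    families <<- lapply(seq_len(config$n_families), function(k) {
      simulate_family(species_tree,
                      sim_params(config$dup_rate, config$loss_rate),
                      family_id = sprintf("fam%d", k))
    })
    names(families) <<- vapply(families, `[[`, "", "family_id")
    alive <- Filter(function(f) !f$extinct, families)
    write_newick_file(lapply(alive, `[[`, "gene_tree"),
                      file.path(config$out_dir, "gene_trees.nwk"))
    jsonlite::write_json(
      lapply(families, function(f)
        list(family = f$family_id, extinct = f$extinct,
             events = f$events)),
      file.path(config$out_dir, "event_logs.json"), auto_unbox = TRUE,
      digits = NA)
    record("simulate", file.path(config$out_dir, "gene_trees.nwk"),
           list(seed = seed_of(1L)))
    record("simulate", file.path(config$out_dir, "event_logs.json"))
  })

  if ("cluster" %in% config$stages) run_stage("cluster", function() {
    alive <- Filter(function(f) !f$extinct, families)
    graph <- simulate_similarity(alive, seed = seed_of(2L))
    pairs_path <- file.path(config$out_dir, "pairs.tsv")
    write_blast_pairs(graph, pairs_path)
    g2 <- build_graph(pairs_path)
    parts <- threshold_profile(g2, config$thresholds)
    tab <- do.call(rbind, lapply(parts, function(p) {
      data.frame(vertex = names(p$membership), threshold = p$threshold,
                 component = unname(p$membership))
    }))
    utils::write.table(tab, file.path(config$out_dir, "partitions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("cluster", pairs_path, list(seed = seed_of(2L)))
    record("cluster", file.path(config$out_dir, "partitions.tsv"))
  })

  if ("reconcile" %in% config$stages) run_stage("reconcile", function() {
    alive <- Filter(function(f) !f$extinct, families)
    recs <<- lapply(alive, function(f) {
      lm <- leaf_species_map(f$gene_tree, species_tree,
                             config$separator, config$position)
      reconcile(f$gene_tree, species_tree, lm,
                cost_weights(config$c_d, config$c_l))
    })
    writeLines(vapply(recs, reconciliation_to_nhx, ""),
               file.path(config$out_dir, "reconciliations.nhx"))
    jsonlite::write_json(lapply(recs, reconciliation_summary),
                         file.path(config$out_dir, "reconciliations.json"),
                         auto_unbox = TRUE, digits = NA)
    record("reconcile", file.path(config$out_dir, "reconciliations.nhx"))
    record("reconcile", file.path(config$out_dir, "reconciliations.json"))
  })

  if ("complements" %in% config$stages) run_stage("complements", function() {
    tab <- complement_table(recs)
    utils::write.table(data.frame(node = rownames(tab), tab,
                                  check.names = FALSE),
                       file.path(config$out_dir, "complements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bursts <- duplication_bursts(recs)
    utils::write.table(bursts, file.path(config$out_dir, "bursts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ortho <- lapply(recs, orthogroups, separator = config$separator,
                    position = config$position)
    pm <- presence_matrix(ortho, species_tree$tip.label,
                          leaf_maps = lapply(recs, `[[`, "leaf_map"))
    utils::write.table(data.frame(species = rownames(pm), pm + 0,
                                  check.names = FALSE),
                       file.path(config$out_dir, "presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("complements", file.path(config$out_dir, "complements.tsv"))
    record("complements", file.path(config$out_dir, "bursts.tsv"))
    record("complements", file.path(config$out_dir, "presence.tsv"))
  })

  if ("support" %in% config$stages) run_stage("support", function() {
    alive <- Filter(function(f) !f$extinct &&
                      length(f$gene_tree$tip.label) >= 4, families)
    if (!length(alive)) {
      message("[support] no family with >= 4 genes; stage skipped")
      return(invisible(NULL))
    }
    ref <- alive[[1]]$gene_tree
    reps <- lapply(seq_len(config$n_replicates), function(k) {
      perturb_tree(ref, config$n_nni, seed = seed_of(3L) + k)
    })
    write_newick_file(reps, file.path(config$out_dir, "replicates.nwk"))
    sup <- branch_supports(ref, reps)
    sup$class <- as.character(classify_support(sup$tbe))
    utils::write.table(sup, file.path(config$out_dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("support", file.path(config$out_dir, "replicates.nwk"),
           list(seed = seed_of(3L)))
    record("support", file.path(config$out_dir, "support.tsv"))
  })

  write_manifest(manifest, config$out_dir)
  invisible(manifest)
}

#' @keywords internal
write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines are
#' ignored; comma-separated values become vectors. Keys mirror the
#' arguments of [run_config()].
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("n_families", "dup_rate", "loss_rate", "c_d", "c_l",
                    "n_replicates", "n_nni", "seed", "thresholds")
  for (k in intersect(names(args), numeric_keys)) {
    args[[k]] <- as.numeric(strsplit(args[[k]], ",", fixed = TRUE)[[1]])
  }
  if ("stages" %in% names(args)) {
    args$stages <- trimws(strsplit(args$stages, ",", fixed = TRUE)[[1]])
  }
  do.call(run_config, args)
}
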