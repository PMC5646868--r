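## End-to-end orchestration: a single config drives synthetic generation,
## structure classification, exploration, trajectory analysis and
## conservation, with a JSON run manifest recording seeds, inputs,
## per-stage status and output digests.

PIPELINE_STAGES <- c("synth", "structure", "explore", "analyze", "conserve")

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  if (is.null(config$seed)) stopf("config schema violation: missing 'seed'")
  if (!is.numeric(config$seed)) stopf("config schema violation: 'seed' must be numeric")
  stages <- config$stages
  if (!is.list(stages) || !length(stages))
    stopf("config schema violation: missing 'stages'")
  unknown <- setdiff(names(stages), PIPELINE_STAGES)
  if (length(unknown))
    stopf("config schema violation: unknown stage(s) '%s'",
          paste(unknown, collapse = "', '"))
  needs_receptor <- any(c("structure", "explore", "analyze") %in%
                          names(stages))
  if (needs_receptor && is.null(stages$synth) &&
      is.null(config$receptor))
    stopf("config schema violation: missing 'receptor' (a PDB path) when no synth stage is requested")
  config
}

digest_files <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the full migration/conservation pipeline from a config
#'
#' Executes the requested stages in dependency order — synthetic-system
#' generation, structure classification (SASA / surface / interface),
#' Monte Carlo exploration, trajectory analysis (RMSF, contacts,
#' energy-distance profile, path assignment) and conservation — writing
#' per-stage TSV outputs under `out_dir` and a `manifest.json` that
#' records the config snapshot, seeds, per-stage status and output file
#' digests. The manifest is written before the stages run (all
#' `pending`) and finalised afterwards; stages not requested are marked
#' `"not requested"`. Re-running with an identical config and seed
#' reproduces byte-identical outputs.
#'
#' @param config a named list or path to a YAML file. Required fields:
#'   `seed` and a `stages` block with any of `synth`, `structure`,
#'   `explore`, `analyze`, `conserve` sub-blocks (each holding that
#'   stage's parameters, e.g. `stages$explore$n_trajectories`).
#' @param out_dir output directory (created if needed).
#' @return the final manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stages <- config$stages
  manifest <- list(
    tool = paste0("ligapath ", as.character(utils::packageVersion("ligapath"))),
    seed = seed,
    config = config,
    stages = setNames(lapply(PIPELINE_STAGES, function(s)
      list(status = if (s %in% names(stages)) "pending" else "not requested",
           outputs = list())), PIPELINE_STAGES))
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function()
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  write_manifest()

  finish <- function(stage, files) {
    manifest$stages[[stage]]$status <<- "done"
    manifest$stages[[stage]]$outputs <<- digest_files(files)
    write_manifest()
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]]$status <<- paste("failed:",
                                              conditionMessage(err))
    write_manifest()
    stopf("stage '%s' failed: %s", stage, conditionMessage(err))
  }

  toy <- NULL
  rec <- NULL
  mig <- NULL

  if (!is.null(stages$synth)) {
    tryCatch({
      p <- stages$synth
      toy <- make_toy_receptor(p$n_res_per_chain %||% 42, seed = seed,
                               spec = p$spec %||% list())
      rec <- toy$receptor
      f_pdb <- file.path(out_dir, "synthetic_receptor.pdb")
      f_paths <- file.path(out_dir, "truth_paths.tsv")
      write_receptor_pdb(rec, f_pdb)
      write_path_definitions(toy$paths, f_paths)
      finish("synth", c(f_pdb, f_paths))
    }, error = function(e) fail("synth", e))
  }

  if (!is.null(stages$structure)) {
    tryCatch({
      p <- stages$structure
      if (is.null(rec))
        rec <- read_receptor(config$receptor, chains = p$chains,
                             cofactor = p$cofactor %||% "FAD")
      surf <- classify_surface_residues(rec,
                                        threshold = p$surface_threshold %||% 0.30,
                                        n_points = p$sasa_points %||% 960)
      intf <- interface_residues(rec, cutoff = p$interface_cutoff %||% 4.0)
      surf$is_interface <- residue_key(surf) %in% residue_key(intf)
      f <- file.path(out_dir, "residue_classification.tsv")
      write.table(surf, f, sep = "\t", quote = FALSE, row.names = FALSE)
      finish("structure", f)
    }, error = function(e) fail("structure", e))
  }

  if (!is.null(stages$explore)) {
    tryCatch({
      p <- stages$explore
      if (is.null(rec))
        rec <- read_receptor(config$receptor)
      oracle <- if (!is.null(toy)) toy$oracle
        else stopf("explore stage needs the synth stage's energy oracle")
      cfg <- migration_config(
        mode = p$mode %||% "exit",
        n_trajectories = p$n_trajectories %||% 20,
        max_steps = p$max_steps %||% 500,
        temperature = p$temperature %||% 1,
        seed = seed)
      lig <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0))
      mig <- explore_migration(rec, lig, oracle, cfg)
      f <- file.path(out_dir, "trajectories.tsv")
      write_trajectories(mig, f)
      finish("explore", f)
    }, error = function(e) fail("explore", e))
  }

  if (!is.null(stages$analyze)) {
    tryCatch({
      if (is.null(mig)) stopf("analyze stage needs the explore stage")
      d <- as.data.frame(mig)
      prof <- energy_distance_profile(d)
      f_prof <- file.path(out_dir, "profile.tsv")
      write.table(prof, f_prof, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths <- if (!is.null(toy)) toy$paths else vao_path_residues()
      labels <- vapply(unique(d$traj_id), function(i) {
        sub <- d[d$traj_id == i, ]
        ct <- contact_table(sub, rec, mig$inputs$ligand_template)
        assign_path(ct, sub, paths, rec)$trajectory_label
      }, character(1))
      f_lab <- file.path(out_dir, "path_assignments.tsv")
      write.table(data.frame(traj_id = unique(d$traj_id), label = labels),
                  f_lab, sep = "\t", quote = FALSE, row.names = FALSE)
      finish("analyze", c(f_prof, f_lab))
    }, error = function(e) fail("analyze", e))
  }

  if (!is.null(stages$conserve)) {
    tryCatch({
      p <- stages$conserve
      al <- if (!is.null(p$msa)) read_msa(p$msa, labels = p$labels,
                                          query = p$query)
        else make_synthetic_msa(seed = seed)$msa
      prof <- conservation_profile(
        al, gap_policy = p$gap_policy %||% "count",
        merged_rule = p$merged_rule %||% "per_subfamily")
      f_prof <- file.path(out_dir, "conservation.tsv")
      write_conservation_tsv(prof, f_prof)
      grp <- group_summary(prof, default_residue_groups(nrow(prof)))
      f_grp <- file.path(out_dir, "group_summary.tsv")
      write_conservation_tsv(grp, f_grp)
      finish("conserve", c(f_prof, f_grp))
    }, error = function(e) fail("conserve", e))
  }

  invisible(manifest)
}
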