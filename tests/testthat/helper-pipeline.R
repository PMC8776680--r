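# Stage a complete file-based pipeline run from one simulation config:
# writes the simulated dataset plus a ground-truth tree placing every
# simulated sequence in its planted clade, and returns a pipeline_config.
prepare_pipeline_run <- function(cfg, dir) {
  sim <- sim_dataset(cfg)
  paths <- write_sim_dataset(sim, dir)
  leaves <- tibble::tibble(leaf_id = sim$truth$seq_id,
                           clade = sim$truth$true_clade)
  st <- sim_tree(leaves, cfg)
  tree_path <- file.path(dir, "tree.nwk")
  refs_path <- file.path(dir, "clade_refs.tsv")
  ape::write.tree(st$tree, tree_path)
  readr::write_tsv(st$references, refs_path)
  config <- pipeline_config(
    fasta = paths[["fasta"]], profile = paths[["profile"]],
    meta = paths[["meta"]], biome = paths[["biome"]],
    taxonomy = paths[["taxonomy"]], features = paths[["features"]],
    focal = paths[["focal"]], tree = tree_path,
    clade_references = refs_path, outdir = file.path(dir, "out"),
    seed = cfg$seed)
  list(sim = sim, config = config)
}
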