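# Shared synthetic worlds, built once per test run and cached. The small
# configuration keeps every per-file test fast; the default configuration is
# used where the study-scale conditions matter.

.world_cache <- new.env(parent = emptyenv())

small_world_config <- function(seed = 7L, ...) {
  synthetic_config(
    seed = seed,
    chrom_lengths = c(chr1 = 1.4e6, chr2 = 1e6),
    n_genes = c(conserved = 60, alternative = 15, a_specific = 8,
                b_specific = 7, unbound = 80, nonortholog = 6),
    n_indeterminate = c(a = 10, b = 10),
    n_background_tes = 60,
    n_blacklist = 2,
    ...
  )
}

get_world <- function(key = c("small", "default_nseq")) {
  key <- match.arg(key)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  w <- switch(key,
    small = build_world(small_world_config()),
    default_nseq = build_world(synthetic_config(seed = 11L),
                               include_sequences = FALSE)
  )
  .world_cache[[key]] <- w
  w
}

get_world_dir <- function() {
  if (!is.null(.world_cache$dir)) return(.world_cache$dir)
  d <- file.path(tempdir(), "orthopeak_test_world")
  write_world(get_world("small"), d)
  .world_cache$dir <- d
  d
}

# classify a world's peaks end to end in memory (no file round trip)
classify_world <- function(world, noise = NULL) {
  cfg <- world$config
  peaks <- emit_replicate_peaks(world, noise = noise)
  high_a <- suppressMessages(remove_blacklisted(
    high_confidence_consensus(peaks$a, 0.01, cfg$species[["a"]]),
    world$blacklist$a))
  high_b <- suppressMessages(remove_blacklisted(
    high_confidence_consensus(peaks$b, 0.01, cfg$species[["b"]]),
    world$blacklist$b))
  low_a <- low_confidence_union(peaks$a, 0.1)
  low_b <- low_confidence_union(peaks$b, 0.1)
  cls <- classify_all_sites(high_a, high_b, low_a, low_b,
                            world$chains_ab, world$chains_ba,
                            pad = cfg$pad,
                            sizes_a = world$sizes_a, sizes_b = world$sizes_b)
  sites_a <- assign_sites_to_genes(cls$sites_a, world$genes_a)
  sites_b <- assign_sites_to_genes(cls$sites_b, world$genes_b)
  ort <- world$orthologs[, c("gene_a", "gene_b")]
  genes <- classify_genes(gene_binding_profiles(sites_a, sites_b, ort))
  list(cls = cls, sites_a = sites_a, sites_b = sites_b, genes = genes)
}
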