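# Shared synthetic fixtures built once per test run: a small random
# genome with an annotation track and an EcoRI-style restriction-site
# track.  Everything is generated in code; no files ship with the tests.

fx <- local({
  g <- gen_genome(c(chrA = 150000, chrB = 50000), gc = 0.5, seed = 101)
  track <- gen_track(g$assembly, coverage = 0.1, mean_len = 500,
                     seed = 102, label = "feat")
  eco <- kmer_track(g$sequences, "GAATTC", label = "ecoRI")
  list(assembly = g$assembly, sequences = g$sequences,
       track = track, eco = eco)
})

tmp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}
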