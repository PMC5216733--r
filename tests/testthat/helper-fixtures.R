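# Shared seeded fixture: the full planted scenario written as pipeline inputs.
write_demo_inputs <- function(dir, seed = 7) {
  ch <- generate_cohort(example_cohort_config(seed = seed))
  write_fixture(ch$set, ch$truth, dir)
  tm <- data.frame(
    mirna = c("hsa-miR-s001", "hsa-miR-s006", "hsa-miR-s006", "hsa-miR-s011"),
    gene = c("TIMELESS", "PER1", "CLOCK", "CRY1")
  )
  write.table(tm, file.path(dir, "targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(
    truth = ch$truth,
    config = pipeline_config(
      expression = file.path(dir, "expression.tsv"),
      samplesheet = file.path(dir, "samplesheet.tsv"),
      target_map = file.path(dir, "targets.tsv"),
      seed = seed
    )
  )
}
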