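# Shared fixtures for the suite. The packaged flume dataset triggers a
# (correct) consistency warning because its individual rates are printed
# at two decimals, too coarse to reproduce I_TOT at the highest
# densities; assemble once here with the warning silenced.
flume_tab <- flume_treatments()

assembled_flume <- suppressWarnings(
  assemble_treatment_table(flume_tab, control = control_spec())
)
assembled_flume$functional_group <- factor(
  assembled_flume$functional_group,
  levels = c("deep", "intermediate_IBB", "shallow")
)

# Small deterministic linear dataset with an exactly known OLS solution.
exact_line <- function(n = 5, c0 = 3, d0 = 2) {
  x <- seq_len(n)
  data.frame(x = x, y = c0 + d0 * x)
}
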