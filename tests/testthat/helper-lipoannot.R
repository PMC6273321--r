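# Shared objects for the suite. Rebuilt per test file; construction is cheap.
reg <- skeleton_registry()
gloss <- named_side_chains()
db_default <- build_database(reg, fa_constraints(), gloss)

# independent re-derivation of a loss combo's total mass from its canonical
# key, used to check chain arithmetic without going through the grammar
loss_key_mass <- function(key) {
  if (key == "FA") return(0)
  parts <- strsplit(key, "+", fixed = TRUE)[[1]][-1]
  unit <- c(CH3OH = monoisotopic_mass("CH4O"), H2O = monoisotopic_mass("H2O"),
            CO = monoisotopic_mass("CO"), BzOH = monoisotopic_mass("C7H6O2"),
            AcOH = monoisotopic_mass("C2H4O2"))
  total <- 0
  for (p in parts) {
    n <- sub("^([0-9]*).*$", "\\1", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + n * unit[[sub("^[0-9]*", "", p)]]
  }
  total
}

random_formula <- function() {
  n <- c(C = sample(0:60, 1), H = sample(0:100, 1),
         N = sample(0:3, 1), O = sample(0:15, 1))
  if (sum(n) == 0) n["C"] <- 1
  elemental_formula(n[n > 0])
}
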