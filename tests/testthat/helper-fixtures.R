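# shared builders for small in-code fixtures

tiny_registry <- function() {
  reg <- registry()
  reg <- register_substance(reg, "64-17-5", "ethanol", "CCO")
  reg <- register_substance(reg, "7647-14-5", "sodium chloride", "[Na+].[Cl-]")
  reg <- register_substance(reg, "127-09-3", "sodium acetate",
                            "CC(=O)[O-].[Na+]")
  reg <- register_substance(reg, "71-43-2", "benzene", "c1ccccc1")
  reg <- register_substance(reg, "50-00-0", "formaldehyde", "C=O")
  reg <- register_substance(reg, "1310-73-2", "sodium hydroxide")  # no SMILES
  reg
}

ann_row <- function(cas, source, code, polarity) {
  data.frame(cas = cas, source = source, hazard_code = code,
             polarity = polarity, stringsAsFactors = FALSE)
}

# corpus of real CAS numbers printed in reference prediction tables
REFERENCE_CAS <- c(
  "107-36-8", "94-47-3", "1660-95-3", "5502-75-0", "90387-74-9",
  "66557-45-7", "877-38-3", "4573-50-6", "104-75-6", "882167-77-3",
  "513-42-8", "25087-26-7", "2210-25-5", "98-95-3", "9009-54-5",
  "1533-45-5", "135-63-7", "103-26-4", "319-86-8", "634-90-2",
  "608-93-5", "933-78-8", "615-50-9", "95-68-1", "23503-68-6",
  "141-16-2", "100-69-6", "24851-98-7", "15356-60-2", "106-96-7",
  "2706-90-3", "85-01-8", "79-41-4", "625-52-5"
)

extdata <- function(file) {
  system.file("extdata", file, package = "toxtriage", mustWork = TRUE)
}
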