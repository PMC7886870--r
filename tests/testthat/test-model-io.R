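test_that("model JSON round-trips and validates the toy example", {
  toy <- toy_model()
  expect_equal(nrow(toy$metabolites), 5)
  expect_length(toy$reactions, 2)
  expect_equal(model_genes(toy), c("G1", "G2", "G3"))

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy, path)
  back <- read_model_json(path)
  expect_equal(back$metabolites$id, toy$metabolites$id)
  expect_equal(back$reactions, toy$reactions)
})

test_that("JSON round-trip reproduces simulated models exactly", {
  for (seed in 1:50) {
    m <- small_random_model(seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_equal(back$metabolites, m$metabolites)
    expect_equal(back$reactions, m$reactions)
  }
})

test_that("model validation rejects single-field corruptions", {
  mets <- data.frame(id = c("A", "B"), stringsAsFactors = FALSE)
  ok <- list(R1 = list(id = "R1", stoichiometry = c(A = -1, B = 1),
                       reversible = FALSE, genes = "G1"))
  expect_s3_class(metabolic_model(mets, ok), "metabolic_model")

  dangling <- ok
  dangling$R1$stoichiometry <- c(A = -1, X = 1)
  expect_error(metabolic_model(mets, dangling), "unknown metabolite.*X")

  zero <- ok
  zero$R1$stoichiometry <- c(A = 0, B = 1)
  expect_error(metabolic_model(mets, zero), "zero or non-finite")

  empty <- ok
  empty$R1$stoichiometry <- numeric(0)
  expect_error(metabolic_model(mets, empty), "empty stoichiometry")

  dup_met <- rbind(mets, data.frame(id = "A"))
  expect_error(metabolic_model(dup_met, ok), "duplicated metabolite")

  expect_error(metabolic_model(mets, list()), "at least one reaction")
})

test_that("DE table loading validates ranges, duplicates and parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tpvalue\tpadj",
               "g1\t2.0\t0.01\t0.04",
               "g2\t0.5\t0.001\t0.01",
               "g3\t-3.1\t0.2\t."), path)
  de <- read_de_table(path)
  expect_equal(nrow(de), 3)
  expect_equal(de$gene, c("G1", "G2", "G3"))  # upper-cased
  expect_true(is.na(de$padj[3]))

  writeLines(c("gene\tlog2fc\tpvalue", "g1\t1\t0.5", "g1\t2\t0.1"), path)
  expect_error(read_de_table(path), "G1")

  writeLines(c("gene\tlog2fc\tpvalue", "g1\t1\t1.2"), path)
  expect_error(read_de_table(path), "\\[0,1\\]")

  writeLines(c("gene\tlog2fc", "g1\t1"), path)
  expect_error(read_de_table(path), "pvalue")
})

test_that("cohort loading drops exactly the non-positive-survival rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_months\tevent\tGCK\tHK2\tUNKNOWN1",
               "s1\t12.5\t1\t10\t5\t1",
               "s2\t0\t1\t3\t2\t2",
               "s3\t30\t0\t0\t8\t3",
               "s4\t8\t1\t2\t2\t4",
               "s5\t2\t0\t1\t1\t5"), path)
  expect_message(coh <- read_cohort(path), "dropped 1 patient")
  expect_equal(nrow(coh), 4)
  expect_equal(attr(coh, "n_dropped"), 1)
  expect_false("s2" %in% coh$sample_id)
  # unknown gene columns are loaded permissively
  expect_true("UNKNOWN1" %in% cohort_genes(coh))

  writeLines(c("sample_id\tos_months\tevent\tGCK",
               "s1\t5\t1\t1", "s1\t6\t0\t2"), path)
  expect_error(suppressMessages(read_cohort(path)), "duplicated sample ids")

  writeLines(c("sample_id\tos_months\tevent\tGCK",
               "s1\t5\t1\t-3"), path)
  expect_error(suppressMessages(read_cohort(path)), "negative or missing")

  writeLines(c("sample_id\tevent\tGCK", "s1\t1\t3"), path)
  expect_error(read_cohort(path), "os_months")
})

test_that("SBML import matches the JSON toy and flattens gene rules", {
  sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="toy">
  <listOfSpecies>
   <species id="A" compartment="c"/><species id="ATP" compartment="c"/>
   <species id="B" compartment="c"/><species id="ADP" compartment="c"/>
   <species id="C" compartment="c"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: g1</p></body></notes>
    <listOfReactants>
     <speciesReference species="A" stoichiometry="1"/>
     <speciesReference species="ATP" stoichiometry="1"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="B" stoichiometry="1"/>
     <speciesReference species="ADP" stoichiometry="1"/>
    </listOfProducts>
   </reaction>
   <reaction id="R2" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (g2 and g3)</p></body></notes>
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="C"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', sbml)
  m <- read_model_sbml(sbml)
  toy <- toy_model()
  expect_equal(m$metabolites$id, toy$metabolites$id)
  expect_equal(lapply(m$reactions, `[[`, "stoichiometry"),
               lapply(toy$reactions, `[[`, "stoichiometry"))
  expect_equal(sort(m$reactions$R2$genes), c("G2", "G3"))

  # fbc-style boolean rule (g1 and g2) or g3 flattens to the full set
  fbc <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1">
 <model id="toy" fbc:strict="false">
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="gp1" fbc:label="g1"/>
   <fbc:geneProduct fbc:id="gp2" fbc:label="g2"/>
   <fbc:geneProduct fbc:id="gp3" fbc:label="g3"/>
  </fbc:listOfGeneProducts>
  <listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <fbc:geneProductAssociation><fbc:or>
      <fbc:and><fbc:geneProductRef fbc:geneProduct="gp1"/>
               <fbc:geneProductRef fbc:geneProduct="gp2"/></fbc:and>
      <fbc:geneProductRef fbc:geneProduct="gp3"/>
    </fbc:or></fbc:geneProductAssociation>
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', fbc)
  m2 <- read_model_sbml(fbc)
  expect_equal(sort(m2$reactions$R1$genes), c("G1", "G2", "G3"))

  # zero reactions is a validation error; missing annotations warn
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><sbml level="2" version="4"><model>
    <listOfSpecies><species id="A"/></listOfSpecies>
    <listOfReactions/></model></sbml>', empty)
  expect_error(read_model_sbml(empty), "no reactions")

  noassoc <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><sbml level="2" version="4"><model>
    <listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>
    <listOfReactions><reaction id="R1">
      <listOfReactants><speciesReference species="A"/></listOfReactants>
      <listOfProducts><speciesReference species="B"/></listOfProducts>
    </reaction></listOfReactions></model></sbml>', noassoc)
  expect_warning(m3 <- read_model_sbml(noassoc), "without parseable gene associations")
  expect_length(m3$reactions$R1$genes, 0)
})
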