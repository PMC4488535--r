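Package: glycopanel
Title: Quantitative Multi-Glycome Profiling from MALDI-TOF Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for absolute quantitative glycomics of N-glycans,
    O-glycans and glycosphingolipid (GSL) glycans measured by MALDI-TOF MS
    after reducing-end derivatization (aoWR glycoblotting or bis-PMP
    labeling). Computes exact monoisotopic masses of derivatized glycans
    from an elemental mass table, enumerates candidate monosaccharide
    compositions for observed peaks within a mass tolerance, converts peak
    areas to picomole amounts through a spiked internal standard,
    classifies species into the standard structural taxonomies
    (pauci-mannose / high-mannose / complex-hybrid N-glycans; ganglio,
    globo and (neo)lacto GSL series; mucin O-glycan cores), simulates
    Y-ion fragmentation and exoglycosidase digestion to resolve isomers
    and sialic-acid linkage proportions, and summarizes multi-stage cell
    panels as fold-change arrow matrices and hierarchical clusterings.
    Includes a synthetic-data generator that renders ground-truth panels
    as noisy peak lists so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
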