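Package: framedock
Title: Blind Rigid Protein-Ligand Docking with Atom Frames and Invariant
    Point Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end blind rigid docking model for protein-ligand
    complexes. Proteins and ligands are embedded into joint single and
    pair representations, processed by an attention trunk with triangle
    updates, and docked by an iterative structure module that attaches a
    local reference frame to every ligand heavy atom and updates ligand
    frames with gated invariant point attention while the protein is held
    fixed. Training uses a docking-specific frame-aligned point error
    together with a Kabsch RMSD loss; evaluation uses symmetry-corrected
    ligand RMSD and the strict 2 Angstrom success rate. Includes a
    binding-affinity head on pooled embeddings, a channel-descriptor
    interpretability pipeline, a deterministic synthetic complex
    generator, and a command-line interface. The network layers and the
    reverse-mode differentiation they train with are implemented in the
    package itself so the whole pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    rlang,
    withr,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
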