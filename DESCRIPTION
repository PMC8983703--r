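Package: zdsurf
Title: 3D Zernike Surface Descriptors for Protein Shape Search and Fold
    Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes rotation-invariant 3D Zernike descriptors (3DZD) of
    molecular surfaces and uses them for protein structure retrieval and
    fold classification. Protein structures (PDB or mmCIF) are converted to
    a triangulated solvent-excluded-surface approximation, voxelized onto a
    cubic grid, and expanded in the orthonormal Zernike-Canterakis basis on
    the unit ball; the norms of the moment sub-vectors form a compact,
    rotation-invariant shape signature (121 values at order 20). Structure
    pairs are scored either by direct descriptor distance or by a trainable
    siamese neural network that outputs the probability that two structures
    share a fold. The package also extracts confident domains from
    predicted models using per-residue pLDDT profiles, assigns coarse
    secondary-structure classes by expert rules or a bagged SVM ensemble,
    and serves ranked nearest-structure queries over a descriptor index,
    with a command-line interface and a synthetic-fixture generator for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
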