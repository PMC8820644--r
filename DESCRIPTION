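Package: redoxscan
Title: Proximity-Based Identification of Redox-Labile Disulfide Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of reducing-probe molecular-dynamics trajectories to
    identify redox-labile (allosteric) disulfide bonds. Implements per-frame
    probe-to-disulfide proximity statistics, the distance and distance+energy
    reduction criteria with ensemble aggregation into per-bond lability
    probabilities, static disulfide geometry profiling (solvent accessibility,
    alpha-carbon distance, the five chi dihedrals and the 20-class disulfide
    conformation taxonomy), trajectory conformational analytics (radius of
    gyration, intramolecular hydrogen bonds, solvent-accessible surface area,
    backbone RMSD, Daura clustering, per-residue deviation maps), the
    control-peptide-normalised percent-reduction statistic for kinetic-trapping
    mass-spectrometry data, and a seeded synthetic probe-diffusion simulator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
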