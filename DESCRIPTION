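Package: lprosy
Title: Looped Projective Spectroscopy (L-PROSY) NMR Simulation and Glycan
    Structural Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates magnetization transfer between labile (hydroxyl, amide)
    and nonlabile protons under chemical exchange with water, comparing
    conventional NOESY/TOCSY mixing with the looped projective spectroscopy
    (L-PROSY) scheme in which short selective excite-evolve-store blocks are
    repeated so that exchange-replenished labile polarization accumulates
    cross-peaks toward their thermodynamic limit. Longitudinal dynamics follow
    a Solomon cross-relaxation plus Bloch-McConnell exchange generator;
    J-mediated TOCSY transfer is propagated in a product-operator Liouville
    space with a stochastic-jump exchange superoperator. Includes schedule
    optimizers and enhancement maps over exchange-rate grids, and the
    structural-NMR toolbox used alongside such experiments: Karplus
    coupling/torsion analysis, r^-6-averaged NOE effective distances,
    geometric hydrogen-bond detection, Arrhenius scaling of exchange rates,
    chemical-shift temperature coefficients, Stejskal-Tanner diffusion fits,
    pairwise 2D-RMSD conformer clustering and torsion population maps for
    multi-model PDB ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    yaml,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
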