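Reference coordinates for the cereblon monomer-vs-dimer worked example.

The check in tests/testthat/test-acceptance.R superposes monomeric CRBN
(PDB entry 8RQ8, chain A) onto its copies in several dimeric entries and
verifies that the C-alpha RMSD after sequence-guided superposition stays
within 2.1 Angstrom, i.e. that the ligand-binding domain behaves as a
rigid body whose pose is conserved between the monomer and its complexes.

The PDB coordinate files are not redistributed with this package. To run
the check, download the entries and place them here as:

    8rq8A.pdb   (monomer)
    4ci1B.pdb  8oizB.pdb  8g66B.pdb  5fqdB.pdb  5hxbC.pdb  6h0gB.pdb  8u16A.pdb

e.g. from https://files.rcsb.org/download/<ENTRY>.pdb (any file holding at
least the named chain is fine; chain selection happens at run time).
Without these files the corresponding acceptance test reports failure with
a pointer to this README.
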