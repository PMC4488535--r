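# Exoglycosidase definitions: enzyme name -> list of "Residue linkage"
# terminal residues removable from non-reducing ends.
alpha2,3-neuraminidase:
  - Neu5Ac a2-3
  - Neu5Gc a2-3
beta1,3-galactosidase:
  - Gal b1-3
beta1,4-galactosidase:
  - Gal b1-4
beta1-3,6-galactosidase:
  - Gal b1-3
  - Gal b1-6
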