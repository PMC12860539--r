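# Example layered-phantom elastic moduli (MPa) for PVC tissue phantoms,
# usable as `simulate` anatomy configs. These are example material sets
# for four-layer cylinder phantoms and three-layer multilayer phantoms;
# boundaries are illustrative since the phantom geometry itself is not
# part of this package.
phantoms:
  cylinder_1:   {moduli: [0.1, 0.05, 0.1, 0.05],        boundaries: [30, 60, 90]}
  cylinder_2:   {moduli: [0.03, 0.015, 0.03, 0.015],    boundaries: [30, 60, 90]}
  cylinder_3:   {moduli: [0.009, 0.0045, 0.009, 0.0045], boundaries: [30, 60, 90]}
  multilayer_1: {moduli: [0.028, 0.014, 0.028],         boundaries: [40, 80]}
  multilayer_2: {moduli: [0.029, 0.0145, 0.029],        boundaries: [40, 80]}
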