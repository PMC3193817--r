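{
 "name": "p2x3_cyclic_10state",
 "states": [
  "R",
  "AR",
  "A2R",
  "A3R",
  "A3Ro",
  "D",
  "AD",
  "A2D",
  "A3D",
  "A3Df"
 ],
 "transitions": [
  {
   "from": "R",
   "to": "AR",
   "rate": "k1",
   "ligand_order": 1
  },
  {
   "from": "AR",
   "to": "R",
   "rate": "l1",
   "ligand_order": 0
  },
  {
   "from": "AR",
   "to": "A2R",
   "rate": "k2",
   "ligand_order": 1
  },
  {
   "from": "A2R",
   "to": "AR",
   "rate": "l2",
   "ligand_order": 0
  },
  {
   "from": "A2R",
   "to": "A3R",
   "rate": "k3",
   "ligand_order": 1
  },
  {
   "from": "A3R",
   "to": "A2R",
   "rate": "l3",
   "ligand_order": 0
  },
  {
   "from": "A3R",
   "to": "A3Ro",
   "rate": "k4",
   "ligand_order": 0
  },
  {
   "from": "A3Ro",
   "to": "A3R",
   "rate": "l4",
   "ligand_order": 0
  },
  {
   "from": "D",
   "to": "AD",
   "rate": "m1",
   "ligand_order": 1
  },
  {
   "from": "AD",
   "to": "D",
   "rate": "n1",
   "ligand_order": 0
  },
  {
   "from": "AD",
   "to": "A2D",
   "rate": "m2",
   "ligand_order": 1
  },
  {
   "from": "A2D",
   "to": "AD",
   "rate": "n2",
   "ligand_order": 0
  },
  {
   "from": "A2D",
   "to": "A3D",
   "rate": "m3",
   "ligand_order": 1
  },
  {
   "from": "A3D",
   "to": "A2D",
   "rate": "n3",
   "ligand_order": 0
  },
  {
   "from": "A3D",
   "to": "A3Df",
   "rate": "m4",
   "ligand_order": 0
  },
  {
   "from": "A3Df",
   "to": "A3D",
   "rate": "n4",
   "ligand_order": 0
  },
  {
   "from": "R",
   "to": "D",
   "rate": "d1",
   "ligand_order": 0
  },
  {
   "from": "D",
   "to": "R",
   "rate": "r1",
   "ligand_order": 0
  },
  {
   "from": "AR",
   "to": "AD",
   "rate": "d2",
   "ligand_order": 0
  },
  {
   "from": "AD",
   "to": "AR",
   "rate": "r2",
   "ligand_order": 0
  },
  {
   "from": "A2R",
   "to": "A2D",
   "rate": "d3",
   "ligand_order": 0
  },
  {
   "from": "A2D",
   "to": "A2R",
   "rate": "r3",
   "ligand_order": 0
  },
  {
   "from": "A3R",
   "to": "A3D",
   "rate": "d4",
   "ligand_order": 0
  },
  {
   "from": "A3D",
   "to": "A3R",
   "rate": "r4",
   "ligand_order": 0
  },
  {
   "from": "A3Ro",
   "to": "A3Df",
   "rate": "d5",
   "ligand_order": 0
  },
  {
   "from": "A3Df",
   "to": "A3Ro",
   "rate": "r5",
   "ligand_order": 0
  }
 ]
}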