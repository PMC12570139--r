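# allopath cluster path geometry
from pymol.cgo import CYLINDER
from pymol import cmd
obj_cluster01_path001 = [ CYLINDER,0.000,0.000,0.000,1.000,0.000,0.000,0.100,0.122,0.467,0.706,0.122,0.467,0.706, CYLINDER,1.000,0.000,0.000,2.000,1.000,0.000,0.250,0.122,0.467,0.706,0.122,0.467,0.706 ]
cmd.load_cgo(obj_cluster01_path001, 'cluster01_path001')
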