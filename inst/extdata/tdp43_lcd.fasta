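>tdp43_lcd offset=261 source=UniProt:Q13148 residues 261-414 (low-complexity domain)
EPKHNSNRQLERSGRFGGNPGGFGNQGGFGNSRGGGAGLGNNQGSNMGGGMNFGAFSINPAMM
AAAQAALQSSWGMMGMLASQQNQSGPSGNNQNQGNMQREPNQAFGSGNNSYSGSNSGAAIGWG
SASNAGSGSGFNGGFGSSMDSKSSGWGM
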