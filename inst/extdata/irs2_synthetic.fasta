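>IRS2_SYNTHETIC synthetic surrogate; single extended D-box planted at 972-980
WDYGAEAICVCVCDTMAHVCKVWNHWVWTHCHKAPQVVKCNDVWKAMVAWQKQTLDNRSE
NEGECHHNIACYNLDDPDIPAADDHAQWGYTQPRCIWEWCTRQCERKLGNYTVIVSCKMV
SMARMGCFKPYAMPWHSFESLNYPAFPSHQIQEPCQQNACQYEFEPQPWFHHPHPGYPWR
LMTRSCMRYNIQYMPIKMRARGLEDHMTGAYRTPMPICQQYLVHPVCGASDSNAGFMAHR
MDVSSFDSPCFYQRNEENGWRWRFPYPLKAQFGGLDMMNFYHWIKVAIDYCWPYYIVVQY
SCWHLPLGYAGVGNWVTHCQHKENHCTPRKWWFAMTVGTRWSHGSIFEFTLTVGKFECIA
FFRSGHTPQIEFQSMSEHIFENWSMNWCKWAFMDLQSTDPGLWAQLNMVPEPESSQHGCL
NERIDKYSEMESTMMWSCDGGPNFKGWHWRAKNMEHPWIAIFKWCLIVDWKMSQNCARLG
RSRYNVIVDCHYSTFPAQPMYLREAWEHWRFVCCAMTANNVYIWIHANGAKYMHISDSQV
SQVYNYSEIIGHLFSTNAVAPFGAYAYDNKAHLFVSCCYTFPCYKRCVESNGKHRSLCFV
YWWNDDLAVQYGGIKCPGGVREGKGEGAPTWLEAEWFVHRDLLQAEHCHWLGFCLSNTIC
EGPNHGIMNLSVDLGCGFKFNVKVMHETDDRITCGWTTQWWSLFGYKGSECVELLTASSF
CDHGRVWFHVRYDTYKMPDHPHRTTYVIEELRFPGTTQWFSIKIEKITLYVLICPRVIQL
CEAHQILAQVPKNAHFHKLNTLMLMQYVYVAHFYYLMSQHISESDKDNAQAACQFDKAVH
FTIPEENIGDKLSVTGMKDFATWADFRYIKRLWGVHEVQAMDYSGNCAATGFMNEKSTLN
FCGFYFMEEMAQTCTQACNWNESAWLKDIQVFERMAPEDAQSVEQNNSFYMCMDADHVPR
VDWEQQDMNEWRTALSEIGNNCITGINHGKCLFCQCFPEDFCAMPNGHPRLCPHAYKWER
LCNPMAFVMHDEPWNSSKFCRWNCGIERYPKNNQQSPLRAPMRPPCSVMLLAWQEEIIPM
SSVTPDVFLVYIPADHKAACVVKINQSLYFSPLNCPVGSDIHALVVQAGIWIVEPPLRRY
WQFKRGPVHDQNPWMGNSDPIWTLTGPMAHASFDSRNEMRSEKKDGHDTTVWNTCDKEKG
AQVIKSCCGMCKWQELPFHMRELPLWDRYYLGAFECTDYPLPWECHHRYASVQKGQEHFC
QKSCGGVFKDLFHWYFAQQTIDAIWHNMCLIHLHNEVNYQWQTYLLYVPPAPPWTPGQGE
IMAGQIASFSQPFELKAR
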