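>papain_synthetic
RFPEYKDLLAQSLVKCLTQTPGGSCLIVELSSPRIDQSLLVTVSGYTFLGTLTMIPAGMK
QLKTGPYWVGESKFGDRRGRAQEIVGLVAYRNEDLMGGIGAQTVVDLFVLGKMWLIKVGD
GMFICKNEFPKPVANRPRFPYDSVQSIFADNSDLREVTHKEHGEIVFDDLDIDENDDDLK
LDTRIIFANMKEVEGETHFYAGFESGIMKSTT
>cathepsinL1_human_synth
MTGGCCRVFSHILRYKDLQSSENSHRRCSNLSAIAGVDYYPMRKWGDKPIRLIILMVYLF
MGVNTYKAGIFTLSKNEIAKRILGQGLPLSHKYTKSLSLVKFPEYSDWLAQRLWKCLTQT
PVGSCRRQEISSPRIDQRRLVTVSGYTFLGQLYMIPAGAKQLKTGPLMVGEVHFGHRRSR
AMEIAILVAYRNECQMMGIGAQGVVHLFVLVNMWLIKMGDGMFCFKEEFAMPADWRPRFP
YDSEQSNYADNSDLDEMVHDEHGFFVFDDLDEGINDDDECLVTRKIFAPMHMVGCIMHFN
NGFEAGGMKSTQ
>cathepsinL2_human_synth
KFPEYSDWLAQRLVYCLTQPPVGSCRRVESTSPRIDQRRLVTVSGYTFLSQTYMIPAGAK
QLKVGPFMVEEVHCGHRRSRAMEIVGACAYRNECLMMGIGAQGVVGLFELDNMWLIKVGD
GCFCFKYKFAMPAAWRPRFKYDSEQSNYADNSDLRELTHDEHGFFVFDDLDEDENDDDLS
LVTRKIFAWNHMVGCIMHTNNGFEAGGMKSTP
>cathepsinB_human_synth
MFRALNRVLTGAFSLQIIRIQVFRSSRTLNPRTGRGMLAIKAQGYLDMIVAIIIELPASA
SRIFPMYKDGQAQGLVDCYRQTYMGSCLIDELASPRIDQWLLETVPGYIFHGTLIMMPAF
YHYLLTGPYPVHKSKFHARRWAAQMPAGLVAFRSEDLMGGIIAQTGGTKTLHHSTGPLQA
GSVLMVMSIVTFFVLGKMWLIKFGDGYIICKNEFVKEAANRQRFLYDGVQSIFADTSPKR
YGMHKLHGEIVWWDLQIDENDTFFKLRWAIPFENMKEVEGNTHFYYDFFEGIEKSTT
>cathepsinF_ref_synth
RNPEYKDVLAQRLPKEWWQTPGGSCIIPELSSEFIDQMLLVTVSGYLIQGTHTGPPAEMK
ILKTGPLMVGENIFGDYIGKAKEIVFLVHNRLGDLKEDIGAQTQQDLFVLTKMNQLKVGD
YRFYCPDPFPKPALSWPRMPYDSVQSIAIDSSDLRELTHKIHYIIVFNELDIDENDDDLK
CDTRIIVANYKPALYETWFSAGFWPGIMKSTT
>cathepsinO_ref_synth
RFPEGPDILARHLFKCFTQTWGGSCLIVEYSYPRADQNLAVTWEGYTFNGNLTMICAGMK
QLKGGPDVVGGCKFGDTRGRAYPIVGCCAYRSLDLGVYIGANNTVDLFPLEKMWLIKVGD
TEFWCSNVTHKPATWRPRFPYMSAQSRFKDNSPLRELHHKEHGHCVFKDLDIDENDDDDK
LDTMWIFHNMKCVEGEGTFYACFDEGQMGSHC
>cathepsinK_ref_synth
YFGEYKYALAMSHVKCLTQTFIGSCVIRYTENMRKLQSLLETVYGYWFDGTLQMIPAGMK
PLITGPSLVYEWKEDDRRSVAQEIVNLYAHIIWDLSPGIIAWKVVDGFKLAKMPPVKVGD
GMFIKKTPHPKPSPNVWPFIMNSVGSPFADNSDVREVTHCEHLEIVSDGLKIDKNSYQVK
LDDRIKHANMLGVEGERHPYAGPEYGIMKSTE
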