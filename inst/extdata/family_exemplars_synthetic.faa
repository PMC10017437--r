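>IS1 synthetic exemplar transposase (119 aa)
MVPFFYCSNTTDMMWGDVWFETAKEMYWIITDSKKLWYMGKANLERPHGWVVWHLQPYDC
KSYETMCAPHVKAMYYGLMHKWVKNRALYWLECPGWKWNPLSMANTPDRHPSLQVIIYY
>IS4 synthetic exemplar transposase (320 aa)
MRMGAFIEFRWKMMSPDACTRHDGRMPKIYPIEGFHHQCTQDLWMPMFMPLSSNPVDSTY
ETEIWLSQHVKRQIRGVEDQFLQLTNLKMINHPKKGLRNHINNLYIHSEIADYGNIWSEP
EMFHLHPPFYVFVEPEYTPDLQQKMTVLWAFTISINRFRNQLVTVFKFRPVYYSLKTWLV
PCGLNQPDTPENYRQVITFWYKPWSHLAQSHVYVTFSTRAALLEIKYCMHTCEDQQYHKC
QWYSNADTNVEKIEDRGYMLWDSQWMNVLQGCNIMTHVQEECIKINWTLTMPKEYLDYNA
DTNLYHMCRPTRQHTTHTPR
>IS5 synthetic exemplar transposase (265 aa)
MYPHVQCSFFKLGAKMWEVTDRTLVPSDGWIVVFTGRTATVVSDMTMRIKRHQLFWTPGW
QPHYTPMKVGQWYPPEIHTGGSDVPKIRCLKRACSDYYMWMNVIPSKDQGIDWRWTRTAH
CFWLWKCLVKGIQGIKGNFLGRVWYASSRGRHSPADLNSHDDKTQPYKCPMRGDLLWCDQ
MWSNFLITTMGRPELFSQQQSMYCQEKWIGQHMFREPFWARNYYDPGTWACGQAYATQRI
CGKVEAQLLTMFDMMLFWYWNYSEW
>IS66 synthetic exemplar transposase (472 aa)
MFRVECRVFCQVMRICWHYGEVHTKQTDDNFGDCQGVVEWHMDPIAMVNGGNQQIIYQYR
WCEARNTVHARWLNCMNARDRTMQWKNFPPDEYWAQGQEWQHSCDTYTGMTWEMQLQKAC
CLGEDSCPFHTRLKWPLAEAEDESYERGHCMAEVMWHCGPHTANPQYQTRTADNFQWHWR
PPMHAEQLGKIMGCDGHPLGTIKKNGIYRKQEGIMEHADECETIPYAEERTIPHWDTWLN
FWNFYWMYRGAYCLSHWKKETENRVSGNWEYFTFHTQDRWADSATGGKLTCPWQRIIERP
CCECTGMRHVSNVRQCTANYAEWIQNYRTPWKTNCQRVIPMWTHDPIWGVPEHSVTTEHW
NNQAYWFYIMQYPVIFLQFHHSGKSQWMDMRWYWQFWYYLDMGCSGHPDDWTQNWKWTGW
SHEDCKLMFAMSYKVTVIIIRDADPMLHCSQWRHQPPWWSKHNISLASKTLG
>IS630 synthetic exemplar transposase (187 aa)
MENAADIPVSLQMHSEWTCSNRCNEEPERIHVTIGKMNPETEEPEVWLGFDLCPNRAEPS
PHLRFTSRKSIGYARIYHWLMLGNHSDHCDPPQGTYEHLVMPNADDEQSLCREHQKFTLR
LFFRRTRGNKCFSGPMDKDKMHLQAEEGGMIYHQGNMTNIPITQDQSPVTDRWWQPGGCC
IHCYIVL
>IS701 synthetic exemplar transposase (432 aa)
MWIYIDFWGMGVKCLFCHWGLNKFMAQYKERPLKWHERRGSRWQYRFSIFMSSSQWTTAR
AVLHSRTRVSIFTKGSKQQCINSRHQTWYWNTWNSQLVCLFESPWAVANQAFVNGCRLNW
WCFDGRDLAPKWFVCHYKYNPFTWISMMDLANFKTFFTDHTKMSHEPWMMECYSLTGFVG
MVHKKDWDNPIGHYAYFPINDLDEYWVSHPFEDVHYWMEKTKCTYCLLRIVNHFTIHRNI
EEEYKQWFKMEMVLFSWWYTSVPAQYKQGTFSQLITKAFDNMPPQTIYMRMHSEEGIENY
GGNCDTVYLGNAHFWLCFYLMWECDVDQFCSCANKQIAIRFWLNRMRLHKNKCWPVHRWL
CIIKPMHYVPTEFLMTVRCLMELAKTYSDREGFVEQLSFFDILFFEDYAYFWCLKMHMCR
GIYEVITNMCRP
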