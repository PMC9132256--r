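{"initial":[0,0.04,0.27,0.39,0.3],"utilities":[0.944687545624228,0.841057537043346,0.591057537043346,0.45272795703383,0.340369874965014],"state_costs":[45.7508081507378,1821.37247834261,1821.37247834261,1821.37247834261,62054.2773033314],"p_unable":[[0,0],[0.259899950502798,0],[0.302378931500213,0.102104813829761],[0.15740083402941,0.248614295342308],[0.0296922953363131,0.0728679831738525]],"annual_wage":56310,"retiree_fraction":0.5,"objective":0.000152575907742416,"transitions":{"TOPS":[{"interval_months":1.5,"entries":[[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549]]},{"interval_months":1.5,"entries":[[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549],[0.000124353493524604,0.673860930713421,0.119000171679808,3.19037696914849e-07,0.207014225075549]]},{"interval_months":3,"entries":[[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06]]},{"interval_months":3,"entries":[[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06]]},{"interval_months":3,"entries":[[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06],[0.490519193095846,1.14681586419455e-06,0.317808820499979,0.191665483909641,5.35567867029131e-06]]},{"interval_months":12,"entries":[[4.7157114305217e-06,2.35650599139352e-07,0.999995027296485,5.33882543830995e-10,2.08076030387272e-08],[0.889037833933553,0.00398663934380442,0.10688444000155,3.78453723176514e-10,9.10863426391002e-05],[0.83101264644911,1.01645470115734e-06,0.168984853399335,1.48335657618799e-06,3.40277569939499e-10],[0.81570296152636,1.99788201069813e-06,6.60365896801948e-11,0.183978294223991,0.000316746301602307],[0.380098444639751,0.0276688247067118,0.589937522624489,0.00163550657180892,0.000659701457239413]]}],"TLIF":[{"interval_months":1.5,"entries":[[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223]]},{"interval_months":1.5,"entries":[[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223],[0.484890869789701,0.0961025943822394,0.00411985395182941,0.00118141472000709,0.413705267156223]]},{"interval_months":3,"entries":[[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09]]},{"interval_months":3,"entries":[[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09]]},{"interval_months":3,"entries":[[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09],[0.390809448516033,0.198414744388285,4.70619101361681e-05,0.410728739037917,6.14762871159758e-09]]},{"interval_months":12,"entries":[[0.149331385365452,0.000122832430332712,0.438959647107067,0.411584960682822,1.17441432675817e-06],[3.41678593857319e-08,3.43126381039938e-10,1.45425836698471e-13,0.999999965419332,6.95366011034065e-11],[2.90377758460885e-06,2.58501327982198e-10,0.999997086523186,9.4383395712945e-09,2.38868556693967e-12],[0.999995380791515,4.18499278281759e-06,9.91087107389422e-10,1.20211310084859e-09,4.32022501788023e-07],[0.000892182252994461,5.26651634885461e-08,0.997312610784557,0.00178759111320881,7.56318407617236e-06]]}]}}
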